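# Shared fixtures, all built in code.

# A uniform-age colony: the queen and n - 1 workers all share `age` at day 0,
# so the colony matches the single-cohort closed form exactly.
uniform_cohort <- function(n, age, duration = 30) {
  ants <- data.frame(
    ant_id = c("queen", sprintf("w%02d", seq_len(n - 1))),
    caste = c("queen", rep("worker", n - 1)),
    eclosion_day = rep(-age, n),
    death_day = NA_real_)
  colony_timeline(ants, duration_days = duration, kind = "fixed")
}

# Minimal excavation_sim carrying just a ledger, for testing the per-ant
# statistics on hand-picked amounts.
fake_sim_with_ledger <- function(amounts, queen_amount = 0) {
  n <- length(amounts)
  ants <- data.frame(
    ant_id = c("queen", sprintf("w%02d", seq_len(n))),
    caste = c("queen", rep("worker", n)),
    eclosion_day = rep(-40, n + 1), death_day = NA_real_)
  structure(list(
    ledger = setNames(c(queen_amount, amounts), ants$ant_id),
    timeline = colony_timeline(ants, 30, "fixed")),
    class = "excavation_sim")
}

# Synthetic nest with three chambers on top and tunnels below; at least
# eight primitives, connected where tunnels meet chambers.
demo_nest_primitives <- function(tunnel_angles = c(80, 75, 85, 50, 55)) {
  data.frame(
    class = c("chamber", "chamber", "chamber",
              rep("tunnel", 5), "wide_tunnel"),
    x_cm = c(10, 22, 32, 8, 14, 22, 28, 33, 18),
    y_cm = c(4, 5, 4, 10, 12, 13, 11, 12, 20),
    orientation_deg = c(4, 0, 6, tunnel_angles, 10),
    width_cm = c(3, 3.5, 2.6, 0.8, 0.9, 0.8, 1.0, 0.9, 1.5),
    length_cm = c(7, 9, 6, 10, 12, 13, 10, 12, 9))
}

# Class ranks shared with synth_nest_mask ground truth.
CLS_RANK <- c(tunnel = 1L, wide_tunnel = 2L, chamber = 3L)

predicted_class_matrix <- function(seg) {
  pred <- matrix(0L, nrow(seg$labels), ncol(seg$labels))
  nz <- seg$labels > 0
  pred[nz] <- CLS_RANK[seg$branches$class[seg$labels[nz]]]
  pred
}
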