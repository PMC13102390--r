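#' Read and write colony timeline files
#'
#' Colony timelines are exchanged as CSV with columns
#' `ant_id, caste, eclosion_day, death_day` (empty `death_day` = alive),
#' one file per colony.
#'
#' @param path file path.
#' @param timeline a [colony_timeline()].
#' @param overwrite allow replacing an existing file.
#' @param ... additional arguments for [colony_timeline()] when reading
#'   (`duration_days`, `kind`, `sampling_days`).
#' @return `read_colony()` returns a [colony_timeline()];
#'   `write_colony()` returns `path` invisibly.
#' @export
read_colony <- function(path, ...) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("ant_id", "caste", "eclosion_day")
  if (!all(need %in% names(df))) {
    stop("colony file must have columns ant_id, caste, eclosion_day")
  }
  if (is.null(df$death_day)) df$death_day <- NA_real_
  df$death_day <- as.numeric(df$death_day)
  colony_timeline(df, ...)
}

#' @rdname read_colony
#' @export
write_colony <- function(timeline, path, overwrite = FALSE) {
  stopifnot(inherits(timeline, "colony_timeline"))
  if (file.exists(path) && !overwrite) stop("file exists; set overwrite = TRUE")
  write.csv(timeline$ants, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and write excavation trajectory files
#'
#' Trajectories are CSV with columns `day, area_cm2, n_ants` (areas in cm2,
#' days as floats).
#'
#' @param path file path.
#' @param trajectory data frame with columns `day`, `area_cm2`, `n_ants`.
#' @param overwrite allow replacing an existing file.
#' @return `read_trajectory()` returns the data frame; `write_trajectory()`
#'   returns `path` invisibly.
#' @export
read_trajectory <- function(path) {
  df <- read.csv(path)
  need <- c("day", "area_cm2", "n_ants")
  if (!all(need %in% names(df))) {
    bad <- setdiff(need, names(df))
    stop(sprintf("%s: missing column(s) %s", path, paste(bad, collapse = ", ")))
  }
  df[order(df$day), need]
}

#' @rdname read_trajectory
#' @export
write_trajectory <- function(trajectory, path, overwrite = FALSE) {
  stopifnot(all(c("day", "area_cm2", "n_ants") %in% names(trajectory)))
  if (file.exists(path) && !overwrite) stop("file exists; set overwrite = TRUE")
  write.csv(trajectory[, c("day", "area_cm2", "n_ants")], path,
            row.names = FALSE)
  invisible(path)
}

#' Read and write binary nest masks as PNG
#'
#' Masks are single-channel PNGs (0 = sand, 255 = excavated) with the pixel
#' scale stored in a JSON sidecar file (`<path>.json`).
#'
#' @param mask a [nest_mask()].
#' @param path PNG file path.
#' @param overwrite allow replacing an existing file.
#' @return `read_mask_png()` returns a [nest_mask()]; `write_mask_png()`
#'   returns `path` invisibly.
#' @export
write_mask_png <- function(mask, path, overwrite = FALSE) {
  stopifnot(inherits(mask, "nest_mask"))
  if (file.exists(path) && !overwrite) stop("file exists; set overwrite = TRUE")
  png::writePNG(mask$mask * 1, path)
  jsonlite::write_json(list(pixel_scale = mask$pixel_scale),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop("missing sidecar file with the pixel scale: ", sidecar)
  }
  meta <- jsonlite::read_json(sidecar)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  nest_mask(img > 0.5, as.numeric(meta$pixel_scale))
}

#' Generate the full synthetic study
#'
#' Mirrors the study design: 22 colony-maturation experiments and 37
#' fixed-demographics experiments (young: group sizes 5/10/15 with
#' n = 4/6/6; old: 6/7/8).
#'
#' @param config a [generator_config()]; its seed governs the whole draw.
#' @param n_maturation number of maturation colonies.
#' @param fixed_design data frame `cohort`, `group_size`, `n` describing the
#'   fixed-demographics arm.
#' @return list with `maturation` (list of timelines) and `fixed` (list of
#'   timelines, each tagged with cohort and group size attributes).
#' @export
synth_study <- function(config = generator_config(seed = 1),
                        n_maturation = 22,
                        fixed_design = data.frame(
                          cohort = rep(c("young", "old"), each = 3),
                          group_size = rep(c(5, 10, 15), 2),
                          n = c(4, 6, 6, 6, 7, 8))) {
  with_seed(config$seed, {
    cfg <- config; cfg$seed <- NULL   # one stream for the whole study
    mat <- replicate(n_maturation, synth_maturation_colony(cfg),
                     simplify = FALSE)
    fixed <- list()
    for (i in seq_len(nrow(fixed_design))) {
      for (j in seq_len(fixed_design$n[i])) {
        tl <- synth_fixed_colony(fixed_design$group_size[i],
                                 fixed_design$cohort[i], cfg)
        fixed[[length(fixed) + 1L]] <- tl
      }
    }
    list(maturation = mat, fixed = fixed)
  })
}

#' Ensemble analysis of excavation trajectories
#'
#' Runs the trajectory-level analyses over a set of observed (or simulated
#' and observed) colony-maturation trajectories: through-origin
#' area-population scaling on the across-colony daily means, asymptotic
#' area per ant, and the lagged cross-correlation between digging rate and
#' population growth rate averaged across colonies.
#'
#' @param trajectories list of data frames `day`, `area_cm2`, `n_ants`.
#' @param max_lag cross-correlation lag range in days.
#' @param smooth_window smoothing window (days) for [rate_series()].
#' @param first_worker_days optional vector of first-worker-emergence days
#'   (one per trajectory) for the `first_worker` stabilization mode.
#' @param seed echoed into the report.
#' @return list of class `colony_analysis`: `scaling` (slope, r_squared),
#'   `area_per_ant` (per-colony values and mean), `xcorr` (mean
#'   coefficients per lag and `peak_lag`), and `config` echo.
#' @export
analyze_colonies <- function(trajectories, max_lag = 30, smooth_window = 3,
                             first_worker_days = NULL, seed = NULL) {
  stopifnot(length(trajectories) >= 1)
  lapply(trajectories, function(tr) {
    if (!all(c("day", "area_cm2", "n_ants") %in% names(tr))) {
      stop("each trajectory needs columns day, area_cm2, n_ants")
    }
  })
  days <- seq(0, max(vapply(trajectories, function(tr) max(tr$day), numeric(1))))
  interp <- function(tr, col) approx(tr$day, tr[[col]], xout = days)$y
  area_mat <- vapply(trajectories, interp, numeric(length(days)), col = "area_cm2")
  n_mat <- vapply(trajectories, interp, numeric(length(days)), col = "n_ants")
  mean_area <- rowMeans(area_mat, na.rm = TRUE)
  mean_n <- rowMeans(n_mat, na.rm = TRUE)
  ok <- is.finite(mean_area) & is.finite(mean_n)
  scaling <- fit_area_vs_population(mean_area[ok], mean_n[ok])

  apa <- vapply(seq_along(trajectories), function(i) {
    tr <- trajectories[[i]]
    fw <- if (!is.null(first_worker_days)) first_worker_days[i] else NULL
    mode <- if (is.null(fw)) "experiment_start" else "first_worker"
    area_per_ant_stabilization(tr$day, tr$area_cm2, tr$n_ants,
                               day1_mode = mode, first_worker_day = fw)
  }, numeric(1))

  ccs <- lapply(trajectories, function(tr) {
    if (nrow(tr) < 3) return(NULL)
    dig <- rate_series(tr$day, tr$area_cm2, smooth_window)
    pop <- rate_series(tr$day, tr$n_ants, smooth_window)
    n <- min(nrow(dig), nrow(pop))
    if (n < 2 * max_lag) return(NULL)
    xcorr_lagged(dig$rate[seq_len(n)], pop$rate[seq_len(n)], max_lag)
  })
  ccs <- Filter(Negate(is.null), ccs)
  xc_mean <- NULL; pk <- NA
  if (length(ccs)) {
    coefs <- vapply(ccs, function(d) d$coefficient, numeric(2 * max_lag + 1))
    xc_mean <- data.frame(lag = ccs[[1]]$lag,
                          coefficient = rowMeans(coefs, na.rm = TRUE))
    pk <- peak_lag(xc_mean)
  }
  structure(list(
    scaling = list(slope = scaling$slope, r_squared = scaling$r_squared),
    area_per_ant = list(values = apa, mean = mean(apa, na.rm = TRUE)),
    xcorr = list(mean = xc_mean, peak_lag = pk, n_colonies = length(ccs)),
    config = list(n_trajectories = length(trajectories), max_lag = max_lag,
                  smooth_window = smooth_window, seed = seed)),
    class = "colony_analysis")
}

#' @export
print.colony_analysis <- function(x, ...) {
  cat("<colony_analysis>\n",
      sprintf("  scaling slope     : %.3f cm2/ant (R2 = %.3f)\n",
              x$scaling$slope, x$scaling$r_squared),
      sprintf("  area per ant      : %.3f cm2/ant (n = %d)\n",
              x$area_per_ant$mean, length(x$area_per_ant$values)),
      sprintf("  xcorr peak lag    : %s d (over %d colonies)\n",
              format(x$xcorr$peak_lag), x$xcorr$n_colonies), sep = "")
  invisible(x)
}

#' Write an analysis or fit report as JSON
#'
#' @param x a `colony_analysis`, `target_line_fit`, `rate_fit`,
#'   `scaling_fit` or `logistic_fit`.
#' @param path output file.
#' @param overwrite allow replacing an existing file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite) stop("file exists; set overwrite = TRUE")
  payload <- if (inherits(x, "colony_analysis")) {
    list(scaling = x$scaling, area_per_ant = x$area_per_ant,
         xcorr = list(peak_lag = x$xcorr$peak_lag,
                      n_colonies = x$xcorr$n_colonies),
         config = x$config)
  } else if (inherits(x, "target_line_fit")) {
    list(estimate = as.list(coef(x)), r_squared = x$r_squared, n = x$n)
  } else if (inherits(x, "rate_fit")) {
    list(estimate = as.list(coef(x)))
  } else if (inherits(x, "scaling_fit")) {
    list(estimate = as.list(coef(x)), r_squared = x$r_squared, n = x$n)
  } else if (inherits(x, "logistic_fit")) {
    list(estimate = as.list(coef(x)))
  } else stop("unsupported report object")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Segment a nest mask end to end
#'
#' Convenience wrapper: skeletonize, segment, classify, and optionally
#' write the branch table (CSV) and a labeled PNG.
#'
#' @param mask a [nest_mask()] or path to a mask PNG with sidecar scale.
#' @param csv,labels_png optional output paths.
#' @param overwrite allow replacing existing files.
#' @param ... passed to [classify_branches()].
#' @return the classified `nest_segmentation`.
#' @export
segment_nest <- function(mask, csv = NULL, labels_png = NULL,
                         overwrite = FALSE, ...) {
  if (is.character(mask)) mask <- read_mask_png(mask)
  seg <- classify_branches(skeletonize_and_segment(mask), ...)
  if (!is.null(csv)) {
    if (file.exists(csv) && !overwrite) stop("file exists; set overwrite = TRUE")
    out <- seg$branches[, c("branch_id", "class", "mean_width_cm",
                            "orientation_deg", "area_cm2")]
    write.csv(out, csv, row.names = FALSE)
  }
  if (!is.null(labels_png)) {
    if (file.exists(labels_png) && !overwrite) {
      stop("file exists; set overwrite = TRUE")
    }
    lut <- c(tunnel = 1 / 3, wide_tunnel = 2 / 3, chamber = 1)
    img <- matrix(0, nrow(seg$labels), ncol(seg$labels))
    nz <- seg$labels > 0
    img[nz] <- lut[seg$branches$class[seg$labels[nz]]]
    png::writePNG(img, labels_png)
  }
  seg
}
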