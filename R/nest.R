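#' Binary nest mask
#'
#' @param mask logical matrix, `TRUE` = excavated pixel. Row 1 is the top of
#'   the image; gravity points toward increasing row index.
#' @param pixel_scale physical size of one pixel in cm.
#' @return an object of class `nest_mask`.
#' @export
nest_mask <- function(mask, pixel_scale) {
  stopifnot(is.matrix(mask), pixel_scale > 0)
  storage.mode(mask) <- "logical"
  structure(list(mask = mask, pixel_scale = pixel_scale),
            class = "nest_mask")
}

#' @export
print.nest_mask <- function(x, ...) {
  cat(sprintf("<nest_mask> %d x %d px at %.3g cm/px, excavated area %.2f cm2\n",
              nrow(x$mask), ncol(x$mask), x$pixel_scale, area_cm2(x)))
  invisible(x)
}

#' Nest photograph
#'
#' @param img numeric array `rows x cols x 3` with values in `[0, 1]`.
#' @param pixel_scale cm per pixel.
#' @param control_points optional matrix (`>= 4` rows) of `(x, y)` pixel
#'   positions of the frame's support blocks, used for registration.
#' @return an object of class `nest_image`.
#' @export
nest_image <- function(img, pixel_scale, control_points = NULL) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3, pixel_scale > 0)
  if (!is.null(control_points)) {
    control_points <- as.matrix(control_points)
    stopifnot(ncol(control_points) == 2, nrow(control_points) >= 4)
  }
  structure(list(img = img, pixel_scale = pixel_scale,
                 control_points = control_points),
            class = "nest_image")
}

#' Excavated area of a mask
#'
#' @param mask a [nest_mask()].
#' @return white-pixel area in cm2: `count(TRUE) * pixel_scale^2`.
#' @export
area_cm2 <- function(mask) {
  stopifnot(inherits(mask, "nest_mask"))
  sum(mask$mask) * mask$pixel_scale^2
}

## ---- homography -----------------------------------------------------------

#' Estimate a projective transformation from point correspondences
#'
#' Direct linear transform with Hartley coordinate normalization, solved by
#' SVD, mapping `src` points onto `dst` points (both `(x, y)`, i.e.
#' (column, row)). Used to register nest photographs on the reference frame
#' via the support blocks as control points.
#'
#' @param src,dst matrices of corresponding points, `n x 2` with `n >= 4`,
#'   not all collinear.
#' @return 3x3 matrix of class `homography`, normalized so `H[3,3] = 1`,
#'   with attribute `rms` (reprojection root-mean-square error in px).
#' @export
estimate_homography <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  stopifnot(ncol(src) == 2, ncol(dst) == 2, nrow(src) == nrow(dst))
  n <- nrow(src)
  if (n < 4) stop("at least 4 correspondences are required")
  collinear <- function(p) {
    s <- svd(scale(p, scale = FALSE))$d
    s[2] < 1e-8 * max(s[1], 1)
  }
  if (collinear(src) || collinear(dst)) stop("control points are collinear")
  normalise <- function(p) {
    ctr <- colMeans(p)
    d <- sqrt(rowSums(sweep(p, 2, ctr)^2))
    s <- sqrt(2) / mean(d)
    T <- rbind(c(s, 0, -s * ctr[1]), c(0, s, -s * ctr[2]), c(0, 0, 1))
    ph <- cbind(p, 1) %*% t(T)
    list(T = T, p = ph[, 1:2, drop = FALSE])
  }
  ns <- normalise(src); nd <- normalise(dst)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- ns$p[i, 1]; y <- ns$p[i, 2]
    u <- nd$p[i, 1]; v <- nd$p[i, 2]
    A[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2 * i, ]     <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  h <- svd(A)$v[, 9]
  H <- solve(nd$T) %*% matrix(h, 3, 3, byrow = TRUE) %*% ns$T
  H <- H / H[3, 3]
  proj <- apply_homography(H, src)
  rms <- sqrt(mean(rowSums((proj - dst)^2)))
  structure(H, class = "homography", rms = rms)
}

#' Apply a homography to points
#'
#' @param H 3x3 projective matrix (class `homography` or plain matrix).
#' @param pts `n x 2` matrix of `(x, y)` points.
#' @return transformed `n x 2` matrix.
#' @export
apply_homography <- function(H, pts) {
  pts <- as.matrix(pts)
  ph <- cbind(pts, 1) %*% t(unclass(H))
  ph[, 1:2, drop = FALSE] / ph[, 3]
}

#' @export
print.homography <- function(x, ...) {
  cat("<homography>\n")
  print(unclass(x)[1:3, 1:3])
  if (!is.null(attr(x, "rms"))) {
    cat(sprintf("reprojection RMS: %.4g px\n", attr(x, "rms")))
  }
  invisible(x)
}

# Bilinear sampling of a single-channel matrix at fractional (x, y) = (col,
# row) positions; outside pixels return `fill`.
bilinear_sample <- function(m, x, y, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  val <- function(col, row) {
    ok <- col >= 1 & col <= nc & row >= 1 & row <= nr
    out <- rep(fill, length(col))
    out[ok] <- m[cbind(row[ok], col[ok])]
    out
  }
  v00 <- val(x0, y0);     v10 <- val(x0 + 1, y0)
  v01 <- val(x0, y0 + 1); v11 <- val(x0 + 1, y0 + 1)
  (v00 * (1 - fx) + v10 * fx) * (1 - fy) + (v01 * (1 - fx) + v11 * fx) * fy
}

#' Register an image onto the reference frame
#'
#' Inverse-maps every output pixel through `H` (which maps source
#' coordinates to reference coordinates) and samples the source image with
#' bilinear interpolation.
#'
#' @param image a [nest_image()].
#' @param H a `homography` mapping image coordinates to the reference frame.
#' @param dim output `(rows, cols)`; defaults to the input size.
#' @return a registered [nest_image()].
#' @export
register <- function(image, H, dim = NULL) {
  stopifnot(inherits(image, "nest_image"))
  d <- dim %||% base::dim(image$img)[1:2]
  Hi <- solve(unclass(H))
  grid <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  srcp <- apply_homography(Hi, cbind(grid$col, grid$row))
  out <- array(0, c(d[1], d[2], 3))
  for (ch in 1:3) {
    out[, , ch] <- matrix(
      bilinear_sample(image$img[, , ch], srcp[, 1], srcp[, 2]),
      nrow = d[1], ncol = d[2])
  }
  cp <- image$control_points
  if (!is.null(cp)) cp <- apply_homography(H, cp)
  nest_image(out, image$pixel_scale, cp)
}

## ---- binarization ---------------------------------------------------------

# Box (moving-window) mean of a matrix via an integral image; window `w` is
# odd; borders use the available (truncated) window.
box_mean <- function(m, w) {
  r <- (w - 1) %/% 2
  nr <- nrow(m); nc <- ncol(m)
  S <- matrix(0, nr + 1, nc + 1)
  S[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  r1 <- pmax(seq_len(nr) - r, 1); r2 <- pmin(seq_len(nr) + r, nr)
  c1 <- pmax(seq_len(nc) - r, 1); c2 <- pmin(seq_len(nc) + r, nc)
  sums <- S[r2 + 1, c2 + 1, drop = FALSE] - S[r1, c2 + 1, drop = FALSE] -
    S[r2 + 1, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
  counts <- outer(r2 - r1 + 1, c2 - c1 + 1)
  sums / counts
}

#' Binarize a registered nest photograph pair into an excavation mask
#'
#' Subtracts the initial (pre-introduction) image from the current one
#' (clipped at zero), takes the per-pixel maximum of the green and blue
#' channels as intensity, applies an adaptive local-mean threshold, and
#' removes speckle components smaller than `min_area_cm2`. Excavated sand
#' appears bright on the backlit photographs, so white (TRUE) pixels are
#' the excavated areas.
#'
#' @param current,initial registered [nest_image()]s of identical geometry.
#' @param window adaptive-threshold window in px (odd; default 51).
#' @param offset threshold offset `c`: a pixel is excavated when its
#'   intensity exceeds the local mean by more than `c` (intensity units,
#'   images in `[0, 1]`).
#' @param min_area_cm2 connected components smaller than this are dropped.
#' @return a [nest_mask()].
#' @export
binarize <- function(current, initial, window = 51, offset = 0.05,
                     min_area_cm2 = 0.5) {
  stopifnot(inherits(current, "nest_image"), inherits(initial, "nest_image"))
  if (!identical(dim(current$img), dim(initial$img))) {
    stop("current and initial images differ in shape")
  }
  diffimg <- pmax(current$img - initial$img, 0)
  intensity <- pmax(diffimg[, , 2], diffimg[, , 3])
  thr <- box_mean(intensity, window) + offset
  m <- intensity > thr
  msk <- nest_mask(m, current$pixel_scale)
  drop_small_components(msk, min_area_cm2)
}

# Remove connected components (8-connectivity) below `min_area_cm2`.
drop_small_components <- function(mask, min_area_cm2) {
  lab <- label_components(mask$mask)
  if (max(lab) == 0L) return(mask)
  px_min <- min_area_cm2 / mask$pixel_scale^2
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= px_min)
  mask$mask <- matrix(lab %in% keep, nrow(mask$mask), ncol(mask$mask))
  mask
}

## ---- pixel-graph utilities ------------------------------------------------

# Label 8-connected components of a logical matrix; returns an integer
# matrix (0 = background).
label_components <- function(m) {
  idx <- which(m)
  out <- matrix(0L, nrow(m), ncol(m))
  if (!length(idx)) return(out)
  nr <- nrow(m)
  pos <- matrix(0L, nrow(m), ncol(m))
  pos[idx] <- seq_along(idx)
  edges <- integer(0)
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    rr <- ((idx - 1L) %% nr) + 1L + d[1]
    cc <- ((idx - 1L) %/% nr) + 1L + d[2]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= ncol(m)
    nb <- rep(0L, length(idx))
    nb[ok] <- pos[cbind(rr[ok], cc[ok])]
    hit <- which(nb > 0L)
    if (length(hit)) edges <- c(edges, rbind(hit, nb[hit]))
  }
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  out[idx] <- as.integer(comp)
  out
}

# Count of 8-neighbours that are TRUE, for every pixel.
neighbor_count <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0L, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- m
  out <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out + p[2:(nr + 1) + dr, 2:(nc + 1) + dc]
  }
  out
}

# Zhang-Suen thinning of a logical matrix to a 1-px-wide skeleton.
zhang_suen <- function(m) {
  m <- m * 1L
  nr <- nrow(m); nc <- ncol(m)
  pad <- function(x) {
    p <- matrix(0L, nr + 2, nc + 2)
    p[2:(nr + 1), 2:(nc + 1)] <- x
    p
  }
  shift <- function(p, dr, dc) p[2:(nr + 1) + dr, 2:(nc + 1) + dc]
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      p <- pad(m)
      P2 <- shift(p, -1, 0); P3 <- shift(p, -1, 1); P4 <- shift(p, 0, 1)
      P5 <- shift(p, 1, 1);  P6 <- shift(p, 1, 0);  P7 <- shift(p, 1, -1)
      P8 <- shift(p, 0, -1); P9 <- shift(p, -1, -1)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      seqs <- list(P2, P3, P4, P5, P6, P7, P8, P9, P2)
      A <- matrix(0L, nr, nc)
      for (i in 1:8) A <- A + (seqs[[i]] == 0L & seqs[[i + 1]] == 1L)
      if (phase == 1) {
        cond <- m == 1L & B >= 2 & B <= 6 & A == 1L &
          (P2 * P4 * P6 == 0L) & (P4 * P6 * P8 == 0L)
      } else {
        cond <- m == 1L & B >= 2 & B <= 6 & A == 1L &
          (P2 * P4 * P8 == 0L) & (P2 * P6 * P8 == 0L)
      }
      if (any(cond)) {
        m[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

# Propagate integer labels (0 = unlabeled) outward within `mask` by repeated
# 8-neighbour dilation; approximates nearest-branch (geodesic) assignment.
propagate_labels <- function(labels, mask) {
  nr <- nrow(labels); nc <- ncol(labels)
  repeat {
    todo <- mask & labels == 0L
    if (!any(todo)) break
    p <- matrix(0L, nr + 2, nc + 2)
    p[2:(nr + 1), 2:(nc + 1)] <- labels
    newlab <- matrix(0L, nr, nc)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nb <- p[2:(nr + 1) + dr, 2:(nc + 1) + dc]
      take <- todo & newlab == 0L & nb > 0L
      newlab[take] <- nb[take]
    }
    if (!any(newlab > 0L)) break   # unreachable pixels (no seed in component)
    labels[newlab > 0L] <- newlab[newlab > 0L]
  }
  labels
}

## ---- segmentation ---------------------------------------------------------

#' Orientation of a pixel path relative to horizontal
#'
#' Principal-axis (PCA) orientation of a set of pixel coordinates, folded
#' into `[0, 90]` degrees: 0 is horizontal, 90 is aligned with gravity
#' (straight down). Folding makes the measure invariant to left-right
#' mirroring.
#'
#' @param path matrix with columns `row`, `col` (>= 2 distinct pixels).
#' @return angle in degrees.
#' @export
branch_orientation <- function(path) {
  path <- as.matrix(path)
  if (nrow(path) < 2) stop("orientation undefined for a single pixel")
  cc <- scale(path, scale = FALSE)
  ev <- eigen(crossprod(cc))$vectors[, 1]
  # ev = (d_row, d_col); angle from horizontal axis
  ang <- atan2(abs(ev[1]), abs(ev[2])) * 180 / pi
  min(max(ang, 0), 90)
}

#' Skeletonize a nest mask and segment it into branches
#'
#' Thins the mask to a one-pixel skeleton (Zhang-Suen), removes junction
#' pixels (3 or more skeleton neighbours) to split the skeleton into
#' branches, merges branches shorter than `min_branch_cm` into the longest
#' adjacent branch, measures each branch's mean width as twice the mean
#' distance-transform value along its path, and assigns every mask pixel to
#' the nearest branch by label propagation inside the mask.
#'
#' @param mask a [nest_mask()].
#' @param min_branch_cm branches with a shorter skeleton path are merged
#'   into an adjacent branch (default 1 cm).
#' @return an object of class `nest_segmentation`: `$branches` (data frame
#'   `branch_id`, `mean_width_cm`, `orientation_deg`, `area_cm2`,
#'   `path_px`), `$labels` (integer matrix assigning every mask pixel to a
#'   branch), `$skeleton`, and the input mask. Classes are added by
#'   [classify_branches()]. An empty mask yields zero branches.
#' @export
skeletonize_and_segment <- function(mask, min_branch_cm = 1) {
  stopifnot(inherits(mask, "nest_mask"))
  m <- mask$mask
  empty <- structure(list(
    branches = data.frame(branch_id = integer(0), mean_width_cm = numeric(0),
                          orientation_deg = numeric(0), area_cm2 = numeric(0),
                          path_px = integer(0)),
    labels = matrix(0L, nrow(m), ncol(m)),
    skeleton = matrix(FALSE, nrow(m), ncol(m)),
    mask = mask), class = "nest_segmentation")
  if (!any(m)) return(empty)
  skel <- zhang_suen(m)
  # compact blobs can thin away entirely (simultaneous-deletion artifact);
  # give every mask component at least its innermost pixel as skeleton
  comp <- label_components(m)
  dmap <- as.matrix(EBImage::distmap(EBImage::Image(m * 1)))
  for (ci in setdiff(unique(comp[comp > 0L]), unique(comp[skel]))) {
    px <- which(comp == ci)
    skel[px[which.max(dmap[px])]] <- TRUE
  }
  nb <- neighbor_count(skel)
  junction <- skel & nb >= 3
  branch_px <- skel & !junction
  lab <- label_components(branch_px)
  # junction pixels join the neighbouring branch so no skeleton pixel is lost
  lab[junction] <- 0L
  lab <- propagate_labels(lab, skel)
  scale_cm <- mask$pixel_scale
  # width from the Euclidean distance transform of the mask
  dm <- as.matrix(EBImage::distmap(EBImage::Image(m * 1)))

  branch_stats <- function(lab, i) {
    path <- which(lab == i, arr.ind = TRUE)
    list(path = path, npix = nrow(path),
         width = 2 * mean(dm[path]) * scale_cm,
         ori = if (nrow(path) >= 2) branch_orientation(path) else NA_real_)
  }

  # merge short branches into the longest adjacent branch
  repeat {
    ids <- sort(unique(lab[lab > 0L]))
    sizes <- vapply(ids, function(i) sum(lab == i), numeric(1))
    small <- ids[sizes * scale_cm < min_branch_cm]
    if (!length(small) || length(ids) == 1L) break
    merged_any <- FALSE
    for (s in small) {
      px <- which(lab == s, arr.ind = TRUE)
      nbr <- adjacent_labels(lab, px, exclude = s)
      if (!length(nbr)) next
      nbr_sizes <- vapply(nbr, function(i) sum(lab == i), numeric(1))
      lab[lab == s] <- nbr[which.max(nbr_sizes)]
      merged_any <- TRUE
    }
    if (!merged_any) break
  }

  # Reconnect corridor fragments split by junction removal: two adjacent
  # branches whose mean widths agree within a factor 1.5 and whose
  # orientations differ by at most 45 degrees are one continuing structure
  # (a tunnel running through a crossing, a chamber spine around an inlet).
  # Perpendicular arms of similar width (a plus junction) stay separate.
  repeat {
    ids <- sort(unique(lab[lab > 0L]))
    if (length(ids) <= 1L) break
    st <- lapply(ids, function(i) branch_stats(lab, i))
    names(st) <- as.character(ids)
    merged_any <- FALSE
    for (i in ids) {
      if (!any(lab == i)) next
      si <- branch_stats(lab, i)
      nbr <- adjacent_labels(lab, si$path, exclude = i)
      for (j in nbr) {
        sj <- branch_stats(lab, j)
        wr <- max(si$width, sj$width) / min(si$width, sj$width)
        dori <- if (is.na(si$ori) || is.na(sj$ori)) 0
                else abs(si$ori - sj$ori)
        if (wr <= 1.5 && dori <= 45) {
          keep <- if (si$npix >= sj$npix) i else j
          drop <- if (keep == i) j else i
          lab[lab == drop] <- keep
          merged_any <- TRUE
          si <- branch_stats(lab, keep)
          i <- keep
        }
      }
    }
    if (!merged_any) break
  }

  ids <- sort(unique(lab[lab > 0L]))
  if (!length(ids)) return(empty)
  lab <- matrix(match(lab, c(0L, ids), nomatch = 1L) - 1L, nrow(lab), ncol(lab))
  ids <- seq_along(ids)
  full <- propagate_labels(lab, m)
  branches <- do.call(rbind, lapply(ids, function(i) {
    s <- branch_stats(lab, i)
    ori <- if (!is.na(s$ori)) s$ori else {
      mp <- which(full == i, arr.ind = TRUE)
      if (nrow(mp) >= 2) branch_orientation(mp) else NA_real_
    }
    data.frame(branch_id = i,
               mean_width_cm = s$width,
               orientation_deg = ori,
               area_cm2 = sum(full == i) * scale_cm^2,
               path_px = s$npix)
  }))
  structure(list(branches = branches, labels = full, skeleton = skel,
                 mask = mask), class = "nest_segmentation")
}

# Labels (excluding `exclude` and 0) within a chessboard distance of 2 of
# the given pixels.
adjacent_labels <- function(lab, px, exclude) {
  nr <- nrow(lab); nc <- ncol(lab)
  found <- integer(0)
  for (dr in -2:2) for (dc in -2:2) {
    rr <- px[, 1] + dr; cc <- px[, 2] + dc
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    v <- lab[cbind(rr[ok], cc[ok])]
    found <- union(found, v[v > 0L & v != exclude])
  }
  found
}

#' @export
print.nest_segmentation <- function(x, ...) {
  cat(sprintf("<nest_segmentation> %d branch(es), %.2f cm2 excavated\n",
              nrow(x$branches), area_cm2(x$mask)))
  if (!is.null(x$branches$class)) {
    print(table(x$branches$class))
  }
  invisible(x)
}

#' @export
plot.nest_segmentation <- function(x, ...) {
  cls <- x$branches$class
  pal <- if (!is.null(cls)) {
    c(tunnel = "#4477aa", wide_tunnel = "#66ccee", chamber = "#ccbb44")
  } else NULL
  lut <- if (is.null(pal)) hcl.colors(max(1, nrow(x$branches)), "Dark 3")
         else unname(pal[cls])
  img <- matrix(NA_integer_, nrow(x$labels), ncol(x$labels))
  img[x$labels > 0] <- x$labels[x$labels > 0]
  image(t(img[rev(seq_len(nrow(img))), , drop = FALSE]), col = lut,
        axes = FALSE, asp = nrow(img) / ncol(img), ...)
  invisible(x)
}

#' Classify branches into tunnels, wide tunnels and chambers
#'
#' Chambers are wide, flat, near-horizontal structures; tunnels are narrow
#' and more vertical. A branch is a chamber when its mean width is at least
#' `w_chamber` and its orientation at most `max_chamber_angle`; otherwise a
#' wide tunnel when its width lies strictly between `w_tunnel` and
#' `w_chamber`; otherwise a tunnel. The width thresholds reflect the ants'
#' body length (roughly 0.8--1.7 cm).
#'
#' @param seg a `nest_segmentation`.
#' @param w_tunnel,w_chamber width thresholds in cm (defaults 1.2 and 2.0).
#' @param max_chamber_angle maximum chamber orientation in degrees from
#'   horizontal (default 30).
#' @return `seg` with a `class` column added to `$branches`.
#' @export
classify_branches <- function(seg, w_tunnel = 1.2, w_chamber = 2.0,
                              max_chamber_angle = 30) {
  stopifnot(inherits(seg, "nest_segmentation"))
  b <- seg$branches
  cls <- rep("tunnel", nrow(b))
  wide <- b$mean_width_cm > w_tunnel & b$mean_width_cm < w_chamber
  cls[wide] <- "wide_tunnel"
  chamber <- b$mean_width_cm >= w_chamber &
    !is.na(b$orientation_deg) & b$orientation_deg <= max_chamber_angle
  cls[chamber] <- "chamber"
  seg$branches$class <- cls
  seg
}

#' Area-weighted orientation histogram of a structural class
#'
#' @param seg a classified `nest_segmentation`.
#' @param class `"tunnel"`, `"wide_tunnel"` or `"chamber"`.
#' @param weight `"area"` (default: each branch weighted by its assigned
#'   area) or `"count"` (each branch counts once).
#' @return data frame `bin_lo`, `bin_hi`, `fraction` over 10-degree bins
#'   from 0 to 90; fractions sum to 1, or all zero (with attribute
#'   `empty = TRUE`) when the class is absent.
#' @export
orientation_histogram <- function(seg, class,
                                  weight = c("area", "count")) {
  weight <- match.arg(weight)
  stopifnot(inherits(seg, "nest_segmentation"))
  if (is.null(seg$branches$class)) stop("run classify_branches() first")
  edges <- seq(0, 90, by = 10)
  out <- data.frame(bin_lo = head(edges, -1), bin_hi = tail(edges, -1),
                    fraction = 0)
  b <- seg$branches[seg$branches$class == class &
                      !is.na(seg$branches$orientation_deg), ]
  if (!nrow(b)) {
    attr(out, "empty") <- TRUE
    return(out)
  }
  bin <- pmin(findInterval(b$orientation_deg, edges, rightmost.closed = TRUE),
              length(edges) - 1L)
  w <- if (weight == "area") b$area_cm2 else rep(1, nrow(b))
  for (i in seq_len(nrow(b))) out$fraction[bin[i]] <- out$fraction[bin[i]] + w[i]
  out$fraction <- out$fraction / sum(out$fraction)
  attr(out, "empty") <- FALSE
  out
}

## ---- synthetic nest masks -------------------------------------------------

#' Rasterize a synthetic nest mask with ground truth
#'
#' Builds a binary mask from geometric primitives -- chambers as oriented
#' ellipses, tunnels and wide tunnels as thick line segments -- along with
#' per-pixel ground-truth class and orientation labels (priority where
#' primitives overlap: chamber > wide tunnel > tunnel).
#'
#' @param primitives data frame with columns `class` (`"tunnel"`,
#'   `"wide_tunnel"`, `"chamber"`), `x_cm`, `y_cm` (centre, y measured
#'   downward from the top), `orientation_deg` (from horizontal, 90 =
#'   straight down), `width_cm`, `length_cm`.
#' @param canvas_cm `(width, height)` of the canvas in cm.
#' @param pixel_scale cm per pixel.
#' @param edge_noise probability of flipping each boundary pixel (default 0).
#' @param seed optional seed for the edge noise.
#' @return list with `mask` (a [nest_mask()]), `labels` (integer matrix:
#'   0 none, 1 tunnel, 2 wide tunnel, 3 chamber), `orientation` (per-pixel
#'   ground-truth orientation, `NA` outside), and the `primitives` echo.
#' @export
synth_nest_mask <- function(primitives, canvas_cm = c(40, 30),
                            pixel_scale = 0.1, edge_noise = 0, seed = NULL) {
  nc <- round(canvas_cm[1] / pixel_scale)
  nr <- round(canvas_cm[2] / pixel_scale)
  lab <- matrix(0L, nr, nc)
  ori <- matrix(NA_real_, nr, nc)
  cls_rank <- c(tunnel = 1L, wide_tunnel = 2L, chamber = 3L)
  if (is.null(primitives) || nrow(primitives) == 0L) {
    return(list(mask = nest_mask(lab > 0L, pixel_scale), labels = lab,
                orientation = ori, primitives = primitives))
  }
  stopifnot(all(primitives$class %in% names(cls_rank)))
  px <- (col(lab) - 0.5) * pixel_scale    # x in cm
  py <- (row(lab) - 0.5) * pixel_scale    # y in cm, downward
  for (i in seq_len(nrow(primitives))) {
    p <- primitives[i, ]
    th <- p$orientation_deg * pi / 180
    # gravity frame: orientation 0 = horizontal, 90 = straight down
    ux <- cos(th); uy <- sin(th)
    dx <- px - p$x_cm; dy <- py - p$y_cm
    along <- dx * ux + dy * uy
    across <- -dx * uy + dy * ux
    inside <- if (p$class == "chamber") {
      (along / (p$length_cm / 2))^2 + (across / (p$width_cm / 2))^2 <= 1
    } else {
      abs(along) <= p$length_cm / 2 & abs(across) <= p$width_cm / 2
    }
    rank_i <- cls_rank[[p$class]]
    take <- inside & (lab < rank_i | lab == 0L)
    lab[take] <- rank_i
    fold <- abs(p$orientation_deg) %% 180
    if (fold > 90) fold <- 180 - fold
    ori[take] <- fold
  }
  m <- lab > 0L
  if (edge_noise > 0) {
    with_seed(seed, {
      nb <- neighbor_count(m)
      boundary <- (m & nb < 8) | (!m & nb > 0)
      flip <- boundary & matrix(runif(length(m)) < edge_noise, nr, nc)
      m[flip] <- !m[flip]
    })
  }
  list(mask = nest_mask(m, pixel_scale), labels = lab, orientation = ori,
       primitives = primitives)
}
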