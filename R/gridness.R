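# Caches keyed by correlogram dimensions: radial bins, center distances and
# bilinear rotation stencils are the same for every map of a given shape.
.grid_cache <- new.env(parent = emptyenv())

#' Lay one embedding unit out on the environment grid
#'
#' @param embedding A `dsi_embedding`.
#' @param env The generating [grid_env()].
#' @param unit Unit (column) index.
#' @param source `"X"` (state vectors, default) or `"W"` (goal vectors).
#' @return A `rate_map`: `height x width` matrix with blocked cells `NA`.
#' @export
rate_map <- function(embedding, env, unit, source = c("X", "W")) {
  source <- match.arg(source)
  M <- embedding[[source]]
  stopifnot(unit >= 1, unit <= ncol(M), nrow(M) == env$n_states)
  map <- matrix(NA_real_, env$height, env$width)
  map[cbind(env$rows, env$cols)] <- M[, unit]
  structure(map, class = c("rate_map", "matrix"), unit = unit, source = source)
}

# Rebuild the free-cell value vector from a rate map (used in tests and for
# the shuffling null).
.map_values <- function(map, env) unname(map[cbind(env$rows, env$cols)])

.values_to_map <- function(values, env) {
  map <- matrix(NA_real_, env$height, env$width)
  map[cbind(env$rows, env$cols)] <- values
  map
}

# FFT plan for masked cross-correlation at all offsets: padded size (highly
# composite, >= 2n - 1 per dimension) and the wrap-around index maps that
# reorder FFT output into offset order -(n-1) .. (n-1).
.fft_plan <- function(h, w) {
  key <- paste0("fft_", h, "x", w)
  if (!is.null(.grid_cache[[key]])) return(.grid_cache[[key]])
  P1 <- stats::nextn(2 * h - 1)
  P2 <- stats::nextn(2 * w - 1)
  ri <- ((-(h - 1)):(h - 1)) %% P1 + 1
  ci <- ((-(w - 1)):(w - 1)) %% P2 + 1
  plan <- list(P1 = P1, P2 = P2, ri = ri, ci = ci)
  .grid_cache[[key]] <- plan
  plan
}

# cc(A, B)[d] = sum_u A[u] B[u + d] for every 2-D offset d, via FFT.
.cc_all <- function(FA, FB, plan) {
  full <- Re(stats::fft(Conj(FA) * FB, inverse = TRUE)) / (plan$P1 * plan$P2)
  full[plan$ri, plan$ci]
}

#' Spatial autocorrelogram of a rate map
#'
#' Pearson correlation of the map with itself at every 2-D offset, computed
#' over the overlapping unmasked cells (FFT-based masked correlation).
#' Offsets with fewer than `min_overlap` overlapping cells (or degenerate
#' variance, e.g. a constant map) are `NA`.
#'
#' @param map A [rate_map()] or plain matrix (NA = masked).
#' @param min_overlap Minimum overlapping cells per offset (default 20).
#' @return `(2h-1) x (2w-1)` correlation matrix of class `autocorrelogram`;
#'   the zero offset sits at the central cell.
#' @export
spatial_autocorrelogram <- function(map, min_overlap = 20) {
  v <- unclass(map)
  attributes(v) <- list(dim = dim(v))
  h <- nrow(v); w <- ncol(v)
  msk <- !is.na(v)
  if (sum(msk) < 2) abort("need at least 2 unmasked cells.")
  mu <- mean(v[msk])
  s <- sd(v[msk])
  out <- matrix(NA_real_, 2 * h - 1, 2 * w - 1)
  if (s == 0) {
    # constant map: correlation undefined everywhere
    return(structure(out, class = c("autocorrelogram", "matrix")))
  }
  plan <- .fft_plan(h, w)
  x <- matrix(0, plan$P1, plan$P2)
  x[seq_len(h), seq_len(w)] <- ifelse(msk, (v - mu) / s, 0)
  x2 <- x^2
  FX <- stats::fft(x)
  FX2 <- stats::fft(x2)
  # the mask terms depend only on the mask, which repeats across the many
  # maps of one environment: cache its FFT and overlap counts
  mkey <- paste0("mask_", h, "x", w, "_", hash(msk))
  mc <- .grid_cache[[mkey]]
  if (is.null(mc)) {
    m <- matrix(0, plan$P1, plan$P2)
    m[seq_len(h), seq_len(w)] <- as.numeric(msk)
    FM <- stats::fft(m)
    mc <- list(FM = FM, n = round(.cc_all(FM, FM, plan)))
    .grid_cache[[mkey]] <- mc
  }
  FM <- mc$FM
  n <- mc$n
  sxy <- .cc_all(FX, FX, plan)
  sx <- .cc_all(FX, FM, plan)   # sum of x over the overlap, anchored side
  sxx <- .cc_all(FX2, FM, plan)
  flip <- function(M) M[rev(seq_len(nrow(M))), rev(seq_len(ncol(M)))]
  sy <- flip(sx)                # shifted side = mirrored offset
  syy <- flip(sxx)
  vx <- n * sxx - sx^2
  vy <- n * syy - sy^2
  ok <- n >= min_overlap & vx > 1e-6 * pmax(n, 1) & vy > 1e-6 * pmax(n, 1)
  out[ok] <- ((n * sxy - sx * sy)[ok]) / sqrt(vx[ok] * vy[ok])
  out[out > 1] <- 1
  out[out < -1] <- -1
  structure(out, class = c("autocorrelogram", "matrix"))
}

.ac_geometry <- function(h, w) {
  key <- paste0("geom_", h, "x", w)
  if (!is.null(.grid_cache[[key]])) return(.grid_cache[[key]])
  cr <- (h + 1) / 2
  cc <- (w + 1) / 2
  rr <- matrix(seq_len(h) - cr, h, w)
  cc_m <- matrix(rep(seq_len(w) - cc, each = h), h, w)
  radius <- sqrt(rr^2 + cc_m^2)
  bins <- round(radius)
  # indicator matrix (bin x cell) for fast radial averaging
  ind <- matrix(0, max(bins) + 1L, length(bins))
  ind[cbind(as.vector(bins) + 1L, seq_along(bins))] <- 1
  geom <- list(radius = radius, bins = bins, max_bin = max(bins),
               bin_indicator = ind)
  .grid_cache[[key]] <- geom
  geom
}

# Bilinear rotation stencil: four source linear indices + weights per target
# cell, NA-propagating. Cached per (dim, angle).
.rotation_stencil <- function(h, w, angle_deg) {
  key <- paste0("rot_", h, "x", w, "_", angle_deg)
  if (!is.null(.grid_cache[[key]])) return(.grid_cache[[key]])
  cr <- (h + 1) / 2
  cc <- (w + 1) / 2
  th <- -angle_deg * pi / 180
  tg <- expand.grid(r = seq_len(h), c = seq_len(w))
  dy <- tg$r - cr
  dx <- tg$c - cc
  sr <- cr + cos(th) * dy - sin(th) * dx
  sc <- cc + sin(th) * dy + cos(th) * dx
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  inb <- r0 >= 1 & r0 + 1 <= h & c0 >= 1 & c0 + 1 <= w
  idx <- function(r, c) (c - 1L) * h + r
  st <- list(
    valid = inb,
    i00 = idx(pmax(r0, 1), pmax(c0, 1)),
    i10 = idx(pmin(pmax(r0, 1) + 1L, h), pmax(c0, 1)),
    i01 = idx(pmax(r0, 1), pmin(pmax(c0, 1) + 1L, w)),
    i11 = idx(pmin(pmax(r0, 1) + 1L, h), pmin(pmax(c0, 1) + 1L, w)),
    w00 = (1 - fr) * (1 - fc), w10 = fr * (1 - fc),
    w01 = (1 - fr) * fc, w11 = fr * fc
  )
  .grid_cache[[key]] <- st
  st
}

#' Gridness score of a spatial autocorrelogram
#'
#' Standard rotational gridness: an annulus around the center is chosen from
#' the radially averaged correlogram (inner radius at its first local
#' minimum, excluding the central peak; outer radius at 2.5 times the first
#' peak radius, clipped to the map). The correlogram restricted to the
#' annulus is correlated with itself rotated by 30/60/90/120/150 degrees;
#' the score is `min(corr at 60, 120) - max(corr at 30, 90, 150)`. Hexagonal
#' fields score high, square lattices negative, rotationally symmetric maps
#' near zero.
#'
#' @param ac An [spatial_autocorrelogram()].
#' @param min_annulus_cells Minimum defined annulus cells per rotation
#'   (default 20); fewer makes the score `NA` (classified non-grid).
#' @return The score (NA when no annulus can be determined), with the
#'   rotation-correlation profile and annulus radii as attributes.
#' @export
gridness_score <- function(ac, min_annulus_cells = 20) {
  h <- nrow(ac); w <- ncol(ac)
  geom <- .ac_geometry(h, w)
  v <- as.vector(ac)
  fin <- is.finite(v)
  sums <- geom$bin_indicator %*% ifelse(fin, v, 0)
  cnts <- geom$bin_indicator %*% as.numeric(fin)
  prof <- as.numeric(sums / cnts)   # index k+1 = radius bin k
  nb <- length(prof)
  if (nb < 4) return(structure(NA_real_, rotation_correlations = NULL))
  cap <- (min(h, w) - 1) / 2   # largest radius with full angular coverage
  # first local minimum after the central peak
  inner <- NA_integer_
  for (k in 2:(nb - 1)) {
    if (!is.finite(prof[k]) || !is.finite(prof[k + 1])) next
    if (prof[k] <= prof[k - 1] && prof[k] < prof[k + 1]) {
      inner <- k - 1L  # radius of bin k
      break
    }
  }
  # sidelobe peak: an interior local maximum clearly above the minimum.
  # A monotone rise ending at the edge of the profile (boundary-overlap
  # artifact of single-field maps) is not a sidelobe; such maps fall back
  # to a full annulus so that every map yields a comparable score (the
  # shuffling null must not condition on apparent structure).
  peak_r <- NA_integer_
  if (!is.na(inner) && inner + 2L <= min(nb, cap) - 1L) {
    after <- seq.int(inner + 2L, min(nb, cap))
    vals <- prof[after]
    if (any(is.finite(vals))) {
      pk <- which.max(ifelse(is.finite(vals), vals, -Inf))
      if (pk < length(after) &&
          prof[after[pk]] - prof[inner + 1] >= 0.05) {
        peak_r <- after[pk] - 1L
      }
    }
  }
  if (!is.na(peak_r)) {
    outer <- min(2.5 * peak_r, cap)
  } else {
    inner <- if (is.na(inner)) 2L else inner
    outer <- cap
  }
  if (outer <= inner) {
    return(structure(NA_real_, rotation_correlations = NULL,
                     inner = inner, outer = outer))
  }
  acv <- as.vector(ac)
  ann <- which(geom$radius >= inner & geom$radius <= outer & is.finite(acv))
  angles <- c(30, 60, 90, 120, 150)
  rc <- setNames(rep(NA_real_, 5), paste0("r", angles))
  for (i in seq_along(angles)) {
    st <- .rotation_stencil(h, w, angles[i])
    rot <- st$w00[ann] * acv[st$i00[ann]] + st$w10[ann] * acv[st$i10[ann]] +
      st$w01[ann] * acv[st$i01[ann]] + st$w11[ann] * acv[st$i11[ann]]
    rot[!st$valid[ann]] <- NA_real_
    sel <- is.finite(rot)
    if (sum(sel) >= min_annulus_cells && sd(acv[ann][sel]) > 1e-12 &&
        sd(rot[sel]) > 1e-12) {
      rc[i] <- cor(acv[ann][sel], rot[sel])
    }
  }
  if (anyNA(rc)) {
    score <- NA_real_
  } else {
    score <- min(rc["r60"], rc["r120"]) - max(rc["r30"], rc["r90"], rc["r150"])
  }
  structure(score, rotation_correlations = rc, inner = inner, outer = outer)
}

# Gridness of a free-cell value vector on env (internal fast path).
.gridness_of_values <- function(values, env, min_overlap = 20) {
  ac <- spatial_autocorrelogram(.values_to_map(values, env), min_overlap)
  as.numeric(gridness_score(ac))
}

#' Classify embedding units as grid-like or not
#'
#' Each unit's rate map gets a gridness score; a null distribution is built
#' by randomly permuting the free-cell values of each map (preserving the
#' value multiset while destroying all spatial layout) and rescoring,
#' pooled over all units. A unit is a grid cell if its score exceeds both
#' the 95th percentile of the pooled null and zero. Units with undefined
#' scores are never classified grid.
#'
#' @param embedding A `dsi_embedding`.
#' @param env The generating [grid_env()].
#' @param n_shuffles Shuffles per unit pooled into the null (>= 100).
#' @param seed Integer seed for the shuffles.
#' @param source `"X"` (default) or `"W"`.
#' @return A tibble with one row per unit (`unit`, `score`, `threshold`,
#'   `is_grid`) and attribute `grid_fraction`; see [grid_fraction()].
#' @export
classify_grid_units <- function(embedding, env, n_shuffles = 100, seed = 1,
                                source = c("X", "W")) {
  source <- match.arg(source)
  if (n_shuffles < 100) abort("`n_shuffles` must be at least 100.")
  M <- embedding[[source]]
  stopifnot(nrow(M) == env$n_states)
  D <- ncol(M)
  n <- env$n_states
  scores <- numeric(D)
  null_scores <- vector("list", D)
  # one stream of permutations shared across units: the pooled null (and
  # hence the classification) is invariant to unit order
  perms <- withr::with_seed(seed, lapply(seq_len(n_shuffles),
                                         function(j) sample.int(n)))
  for (u in seq_len(D)) {
    v <- M[, u]
    scores[u] <- .gridness_of_values(v, env)
    ns <- numeric(n_shuffles)
    for (j in seq_len(n_shuffles)) {
      ns[j] <- .gridness_of_values(v[perms[[j]]], env)
    }
    null_scores[[u]] <- ns
  }
  pooled <- unlist(null_scores)
  pooled <- pooled[is.finite(pooled)]
  threshold <- if (length(pooled) > 0) quantile(pooled, 0.95, names = FALSE) else Inf
  is_grid <- !is.na(scores) & scores > pmax(threshold, 0)
  out <- tibble::tibble(unit = seq_len(D), score = scores,
                        threshold = threshold, is_grid = is_grid)
  attr(out, "grid_fraction") <- mean(is_grid)
  attr(out, "source") <- source
  out
}

#' Fraction of units classified as grid cells
#'
#' @param classification Output of [classify_grid_units()].
#' @return Fraction in `[0, 1]`.
#' @export
grid_fraction <- function(classification) {
  attr(classification, "grid_fraction") %||% mean(classification$is_grid)
}

#' Plot a rate map
#'
#' @param object A [rate_map()].
#' @param ... Unused.
#' @return A ggplot raster of the unit's activity over the room.
#' @export
autoplot.rate_map <- function(object, ...) {
  df <- expand.grid(row = seq_len(nrow(object)), col = seq_len(ncol(object)))
  df$value <- as.vector(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(na.value = "grey80") +
    ggplot2::labs(title = sprintf("unit %s (%s)", attr(object, "unit"),
                                  attr(object, "source")),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
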