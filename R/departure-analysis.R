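# The +/- 3 day departure counterfactual: re-run the wind annotation with
# the whole schedule shifted in time (identical route geometry, no
# re-routing), bin per-step tailwinds by latitude, and compare each offset
# against the actual departure date.  Negative differences mean the actual
# departure gave better en-route winds than the alternative.

#' Departure-analysis configuration
#'
#' @param offsets Integer day offsets; must contain 0 (the actual
#'   departure).
#' @param bin_edges Latitude bin edges, degrees, strictly increasing.
#' @param gain_band Latitude band (degrees) over which the seasonal wind
#'   gain is computed.
#' @param n_perm Permutations for the sign-flip test.
#' @param seed Seed for permutation draws.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(offsets = -3:3, bin_edges = seq(0, 70, by = 5),
                            gain_band = c(25, 55), n_perm = 1000, seed = 1) {
  if (!0 %in% offsets) stop("offsets must contain 0")
  if (any(diff(bin_edges) <= 0)) stop("bin edges must be strictly increasing")
  structure(list(offsets = sort(unique(as.integer(offsets))),
                 bin_edges = bin_edges, gain_band = gain_band,
                 n_perm = n_perm, seed = seed),
            class = "analysis_config")
}

#' Shift a schedule in time
#'
#' Advances every date by `offset` days; the spatial route and segment
#' structure are unchanged.
#'
#' @param track A per-bird track data frame.
#' @param offset Whole days (positive = later departure).
#' @return The shifted track.
#' @export
shift_departure <- function(track, offset) {
  track$date <- track$date + as.integer(offset)
  track
}

#' @rdname shift_departure
#' @param segments A segment table to shift alongside its track.
#' @export
shift_segments <- function(segments, offset) {
  segments$start_date <- segments$start_date + as.integer(offset)
  segments$end_date <- segments$end_date + as.integer(offset)
  segments
}

#' Counterfactual en-route tailwinds for shifted departures
#'
#' For each bird and offset, annotates the time-shifted schedule with the
#' identical level-selection rules, assigns per-step tailwinds to latitude
#' bins by step midpoint, and differences each offset against the actual
#' departure (offset 0).
#'
#' @param tracks Multi-bird track data frame (or a single bird's track).
#' @param segments Segment table covering the same birds.
#' @param field A `wind_field` covering all shifted schedules.
#' @param config An [analysis_config()].
#' @param wind_cfg A [wind_config()].
#' @return A list of class `counterfactual_result`:
#'   \describe{
#'     \item{per_bird}{`bird_id`, `offset`, `bin_mid`, `mean_tailwind`,
#'       `delta`, `n` (empty bird/offset/bin combinations keep `n = 0` and
#'       `NA` values, never zero);}
#'     \item{per_offset_bin}{mean `delta` over birds;}
#'     \item{per_bin}{mean `delta` over birds and the nonzero offsets.}
#'   }
#' @export
counterfactual_tailwinds <- function(tracks, segments, field,
                                     config = analysis_config(),
                                     wind_cfg = wind_config()) {
  birds <- split_birds(tracks)
  seg_birds <- if ("bird_id" %in% names(segments)) {
    split(segments, segments$bird_id)
  } else {
    stats::setNames(list(segments), names(birds))
  }
  mids <- (config$bin_edges[-1] + config$bin_edges[-length(config$bin_edges)]) / 2
  rows <- list()
  for (id in names(birds)) {
    tr <- birds[[id]]
    sg <- seg_birds[[id]]
    per_offset <- list()
    for (o in config$offsets) {
      steps <- tryCatch(
        annotate_track(shift_departure(tr, o), shift_segments(sg, o),
                       field, wind_cfg),
        error = function(e) {
          warning("bird ", id, " offset ", o, " dropped: ",
                  conditionMessage(e), call. = FALSE)
          NULL
        })
      if (is.null(steps) || nrow(steps) == 0L) next
      bl <- tailwind_by_latitude(steps, config$bin_edges)
      per_offset[[as.character(o)]] <-
        data.frame(bird_id = id, offset = o, bin_mid = bl$bin_mid,
                   mean_tailwind = bl$mean_tailwind, n = bl$n)
    }
    if (!"0" %in% names(per_offset)) next
    base <- per_offset[["0"]]
    for (o in names(per_offset)) {
      po <- per_offset[[o]]
      po$delta <- ifelse(po$n > 0 & base$n > 0,
                         po$mean_tailwind - base$mean_tailwind, NA_real_)
      rows[[paste(id, o)]] <- po
    }
  }
  per_bird <- do.call(rbind, rows)
  rownames(per_bird) <- NULL
  occupied <- per_bird[!is.na(per_bird$delta), , drop = FALSE]
  per_offset_bin <- stats::aggregate(delta ~ offset + bin_mid, occupied, mean)
  nz <- occupied[occupied$offset != 0, , drop = FALSE]
  per_bin <- stats::aggregate(delta ~ bin_mid, nz, mean)
  names(per_bin)[names(per_bin) == "delta"] <- "mean_delta"
  structure(list(per_bird = per_bird, per_offset_bin = per_offset_bin,
                 per_bin = per_bin),
            class = "counterfactual_result")
}

#' Sign-flip permutation test for paired offset differences
#'
#' Omnibus test of whether departure offset matters: each bird's whole
#' difference vector keeps or flips its sign as a unit (preserving
#' within-bird structure), and the observed statistic - the sum of squared
#' per-offset mean differences - is compared against its permutation
#' distribution (one-sided: large values indicate an offset effect).  A
#' squared statistic is used because offset effects need not share a sign
#' across offsets (e.g. a temporal ramp moves opposite offsets in opposite
#' directions).
#'
#' @param diffs Matrix of per-bird differences (birds x offsets) or a
#'   vector (one difference per bird).  Birds with missing rows are
#'   dropped.
#' @param n_perm Number of permutations.
#' @param seed Seed.
#' @return A list: `statistic` (observed sum of squared per-offset means),
#'   `p_value`.
#' @export
sign_flip_test <- function(diffs, n_perm = 1000, seed = 1) {
  d <- as.matrix(diffs)
  d <- d[stats::complete.cases(d), , drop = FALSE]
  b <- nrow(d)
  if (b < 2L) stop("need at least 2 birds")
  obs <- sum(colMeans(d)^2)
  set.seed(derive_seed(seed, 29L))
  flips <- matrix(sample(c(-1, 1), n_perm * b, replace = TRUE), n_perm, b)
  perm_means <- (flips %*% d) / b
  perm <- rowSums(perm_means^2)
  list(statistic = obs,
       p_value = (1 + sum(perm >= obs - 1e-12)) / (n_perm + 1))
}

#' Tailwind at the departure location under shifted departure dates
#'
#' For each bird and offset, samples the tailwind the bird would have
#' encountered at its departure location on `departure_date + offset`,
#' along the azimuth of its first travel step, at the best allowed flight
#' level; then tests "offset matters" with the sign-flip permutation test
#' on per-bird (offset minus actual) differences.
#'
#' @param tracks Multi-bird track data frame (>= 5 birds).
#' @param segments Segment table covering the same birds.
#' @param field A `wind_field`.
#' @param config An [analysis_config()] (needs >= 2 offsets).
#' @param wind_cfg A [wind_config()].
#' @return A list of class `departure_test_result`: `tailwinds` (birds x
#'   offsets matrix), `diffs` (vs offset 0), `statistic`, `p_value`.
#' @export
departure_location_winds <- function(tracks, segments, field,
                                     config = analysis_config(),
                                     wind_cfg = wind_config()) {
  if (length(config$offsets) < 2L) stop("need at least 2 offsets")
  birds <- split_birds(tracks)
  if (length(birds) < 5L) stop("need at least 5 birds")
  seg_birds <- split(segments, segments$bird_id)
  tw <- matrix(NA_real_, length(birds), length(config$offsets),
               dimnames = list(names(birds), config$offsets))
  for (bi in seq_along(birds)) {
    tr <- interpolate_equinox(birds[[bi]])
    sg <- seg_birds[[names(birds)[bi]]]
    trav <- sg[sg$kind == "travel", , drop = FALSE]
    if (nrow(trav) == 0L) next
    dep_date <- trav$start_date[1]
    i <- match(dep_date, tr$date)
    if (is.na(i) || i >= nrow(tr)) next
    for (oi in seq_along(config$offsets)) {
      prof <- tryCatch(
        tailwind_profile(field, tr$lat[i], tr$lon[i], tr$lat[i + 1],
                         tr$lon[i + 1], dep_date + config$offsets[oi],
                         wind_cfg$levels),
        error = function(e) NULL)
      if (is.null(prof)) next
      tw[bi, oi] <- select_flight_level(prof, wind_cfg$allowed_range)$tailwind
    }
  }
  zero_col <- match(0L, config$offsets)
  diffs <- tw[, -zero_col, drop = FALSE] - tw[, zero_col]
  test <- sign_flip_test(diffs, n_perm = config$n_perm, seed = config$seed)
  structure(list(tailwinds = tw, diffs = diffs,
                 statistic = test$statistic, p_value = test$p_value),
            class = "departure_test_result")
}

#' Seasonal wind-support gain
#'
#' Percentage gain of spring over autumn mean tailwind across latitude bins
#' inside `band`: `100 * (mean_spring - mean_autumn) / mean_autumn`, each
#' season averaged over its occupied bins.  When the autumn band mean is
#' not positive the ratio is reported as undefined (`NA` gain), never
#' silently clipped.
#'
#' @param spring,autumn Data frames from [tailwind_by_latitude()].
#' @param band Latitude band `c(south, north)`, degrees.
#' @return A list: `gain_percent` (`NA` if undefined), `mean_spring`,
#'   `mean_autumn`, `defined`.
#' @export
wind_gain_percent <- function(spring, autumn, band = c(25, 55)) {
  inb <- function(x) x$bin_mid >= band[1] & x$bin_mid <= band[2] & x$n > 0
  s <- spring[inb(spring), , drop = FALSE]
  a <- autumn[inb(autumn), , drop = FALSE]
  if (nrow(s) == 0L || nrow(a) == 0L) {
    stop("no occupied bins within the band for one of the seasons")
  }
  ms <- mean(s$mean_tailwind)
  ma <- mean(a$mean_tailwind)
  if (ma <= 0) {
    return(list(gain_percent = NA_real_, mean_spring = ms, mean_autumn = ma,
                defined = FALSE))
  }
  list(gain_percent = 100 * (ms - ma) / ma, mean_spring = ms,
       mean_autumn = ma, defined = TRUE)
}
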