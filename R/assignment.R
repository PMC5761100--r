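#' Natal-assignment probability surface for one bird
#'
#' For every valid cell inside the species range the unnormalized
#' likelihood is the normal density of the observed feather d2H at the
#' cell's feather-isoscape mean with the cell's combined SD.  The surface
#' is then range-masked and normalized to unit total mass.  The likelihood
#' is accumulated in log space with max-subtraction before exponentiation,
#' so steep surfaces on large grids do not underflow.
#'
#' @param feather_d2h observed feather value (permil).
#' @param feather_surface `iso_raster`, feather-isoscape mean (permil).
#' @param feather_sd_surface `iso_raster`, combined SD (permil); every
#'   masked-in cell must have SD strictly positive.
#' @param mask `iso_range_mask`.
#' @param bird_id optional identifier carried on the result.
#' @return an object of class `assignment_surface`: `bird_id`, `probs`
#'   (`iso_raster`, nodata outside the range, valid cells summing to 1).
#' @export
likelihood_surface <- function(feather_d2h, feather_surface,
                               feather_sd_surface, mask, bird_id = "") {
  stopifnot(is.numeric(feather_d2h), length(feather_d2h) == 1L,
            is.finite(feather_d2h))
  stop_if_misaligned(feather_surface, feather_sd_surface,
                     "feather mean and SD surfaces")
  mu <- apply_mask(feather_surface, mask)$values
  sg <- apply_mask(feather_sd_surface, mask)$values
  valid <- is.finite(mu) & is.finite(sg)
  if (!any(valid))
    stop("empty support: no valid cells remain after masking", call. = FALSE)
  if (any(sg[valid] <= 0))
    stop("sd surface has non-positive cells inside the range; ",
         "assignment requires strictly positive SDs", call. = FALSE)
  loglik <- matrix(NA_real_, nrow(mu), ncol(mu))
  loglik[valid] <- stats::dnorm(feather_d2h, mu[valid], sg[valid], log = TRUE)
  m <- max(loglik[valid])
  probs <- matrix(NA_real_, nrow(mu), ncol(mu))
  probs[valid] <- exp(loglik[valid] - m)
  probs[valid] <- probs[valid] / sum(probs[valid])
  structure(list(bird_id = bird_id,
                 probs = raster_like(feather_surface, probs)),
            class = "assignment_surface")
}

#' @export
print.assignment_surface <- function(x, ...) {
  v <- x$probs$values
  cat(sprintf("<assignment_surface> bird '%s': %d support cells, max p = %.3g, total = %.9f\n",
              x$bird_id, sum(is.finite(v)), max(v, na.rm = TRUE),
              sum(v, na.rm = TRUE)))
  invisible(x)
}

#' Probability-weighted spatial centroid of the top-probability cells
#'
#' Ranks the surface's valid cells by probability, retains the top
#' `ceiling(top_fraction * n_valid)` cells, draws `n_resample` cells from
#' the retained set (uniformly; with replacement only when the retained set
#' is smaller than `n_resample`), and returns the probability-weighted mean
#' of the resampled cells' center coordinates.  The study defaults are the
#' top 10% of cells resampled to 100 values.
#'
#' @param surface an `assignment_surface`.
#' @param top_fraction proportion in (0, 1] of valid cells to retain.
#' @param n_resample number of cells drawn from the retained set.
#' @param seed integer seed; the centroid is deterministic under a fixed
#'   seed.
#' @param weighted_draw draw cells with probability weights instead of
#'   uniformly (off by default).
#' @return an object of class `assignment_centroid`: `bird_id`, `lat`,
#'   `lon`, `mean_top_prob`, `n_cells_top`, `n_resampled`, `seed`.
#' @export
centroid_top_fraction <- function(surface, top_fraction = 0.10,
                                  n_resample = 100, seed = 1L,
                                  weighted_draw = FALSE) {
  stopifnot(inherits(surface, "assignment_surface"))
  if (!is.numeric(top_fraction) || top_fraction <= 0 || top_fraction > 1)
    stop("usage error: top_fraction must lie in (0, 1]", call. = FALSE)
  assert_count(n_resample, "n_resample")
  g <- surface$probs
  idx <- which(is.finite(g$values), arr.ind = TRUE)
  p <- g$values[idx]
  n_top <- ceiling(top_fraction * length(p))
  ord <- order(p, decreasing = TRUE)
  top <- ord[seq_len(n_top)]
  withr::with_seed(as.integer(seed), {
    draw <- if (length(top) == 1L) rep(1L, n_resample)
    else sample.int(length(top), n_resample,
                    replace = length(top) < n_resample,
                    prob = if (weighted_draw) p[top] else NULL)
  })
  chosen <- top[draw]
  ctr <- cell_center(g, idx[chosen, 1], idx[chosen, 2])
  if (is.null(dim(ctr))) ctr <- matrix(ctr, 1L, dimnames = list(NULL, c("lon", "lat")))
  w <- p[chosen] / sum(p[chosen])
  structure(list(bird_id = surface$bird_id,
                 lat = sum(w * ctr[, "lat"]),
                 lon = sum(w * ctr[, "lon"]),
                 mean_top_prob = mean(p[chosen]),
                 n_cells_top = n_top,
                 n_resampled = as.integer(n_resample),
                 seed = as.integer(seed)),
            class = "assignment_centroid")
}

#' @export
print.assignment_centroid <- function(x, ...) {
  cat(sprintf("<assignment_centroid> bird '%s': lat %.3f, lon %.3f (top %d cells, %d resampled)\n",
              x$bird_id, x$lat, x$lon, x$n_cells_top, x$n_resampled))
  invisible(x)
}

#' Assign a whole cohort of migrants
#'
#' Runs [likelihood_surface()] and [centroid_top_fraction()] for each bird.
#' Per-bird seeds are derived deterministically from the master seed and
#' the bird id, so any bird can be re-run in isolation.  Per-bird failures
#' are collected and reported without aborting the cohort.
#'
#' @param migrants data frame with columns `bird_id` and `feather_d2h`.
#' @param feather_surface,feather_sd_surface feather isoscape mean and SD
#'   (`iso_raster`).
#' @param mask `iso_range_mask`.
#' @param top_fraction,n_resample,weighted_draw see
#'   [centroid_top_fraction()].
#' @param seed master seed.
#' @return list with `surfaces` (named list of `assignment_surface`),
#'   `centroids` (data frame: bird_id, lat, lon, mean_top_prob,
#'   n_cells_top, n_resampled), and `failed` (data frame of bird_id +
#'   message for any failures).
#' @export
assign_cohort <- function(migrants, feather_surface, feather_sd_surface,
                          mask, top_fraction = 0.10, n_resample = 100,
                          seed = 1L, weighted_draw = FALSE) {
  stopifnot(is.data.frame(migrants), nrow(migrants) >= 1L,
            all(c("bird_id", "feather_d2h") %in% names(migrants)))
  surfaces <- list()
  cent_rows <- list()
  failures <- list()
  for (i in seq_len(nrow(migrants))) {
    id <- as.character(migrants$bird_id[i])
    res <- tryCatch({
      s <- likelihood_surface(migrants$feather_d2h[i], feather_surface,
                              feather_sd_surface, mask, bird_id = id)
      ctr <- centroid_top_fraction(s, top_fraction = top_fraction,
                                   n_resample = n_resample,
                                   seed = derive_seed(seed, id),
                                   weighted_draw = weighted_draw)
      list(surface = s, centroid = ctr)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[id]] <- conditionMessage(res)
    } else {
      surfaces[[id]] <- res$surface
      ctr <- res$centroid
      cent_rows[[id]] <- data.frame(bird_id = id, lat = ctr$lat,
                                    lon = ctr$lon,
                                    mean_top_prob = ctr$mean_top_prob,
                                    n_cells_top = ctr$n_cells_top,
                                    n_resampled = ctr$n_resampled)
    }
  }
  if (length(failures))
    warning(sprintf("assignment failed for %d bird(s): %s",
                    length(failures),
                    paste(names(failures), collapse = ", ")),
            call. = FALSE)
  list(surfaces = surfaces,
       centroids = if (length(cent_rows)) do.call(rbind, c(cent_rows, list(make.row.names = FALSE)))
                   else data.frame(),
       failed = if (length(failures))
         data.frame(bird_id = names(failures),
                    message = unlist(failures), row.names = NULL)
       else data.frame(bird_id = character(), message = character()))
}
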