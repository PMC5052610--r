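#' Band-intensity table for a DGGE gel
#'
#' Holds a lane-by-band matrix of non-negative band intensities as quantified
#' from a denaturing gradient gel, one lane per sample (e.g. reactor
#' compartment and stage).
#'
#' @param intensities numeric matrix (lanes in rows, bands in columns),
#'   entries non-negative.
#' @param lane_ids lane labels; default taken from rownames or generated.
#' @param band_ids band labels; default taken from colnames or generated.
#' @return An object of class `band_table`.
#' @export
band_table <- function(intensities, lane_ids = NULL, band_ids = NULL) {
  intensities <- as.matrix(intensities)
  if (!is.numeric(intensities) || any(is.na(intensities)))
    stop("`intensities` must be a numeric matrix without NAs", call. = FALSE)
  if (any(intensities < 0))
    stop("band intensities must be non-negative", call. = FALSE)
  if (is.null(lane_ids))
    lane_ids <- rownames(intensities) %||% paste0("lane", seq_len(nrow(intensities)))
  if (is.null(band_ids))
    band_ids <- colnames(intensities) %||% paste0("band", seq_len(ncol(intensities)))
  if (length(lane_ids) != nrow(intensities) || length(band_ids) != ncol(intensities))
    stop("label lengths must match the intensity matrix", call. = FALSE)
  dimnames(intensities) <- list(lane_ids, band_ids)
  structure(list(intensities = intensities,
                 lane_ids = as.character(lane_ids),
                 band_ids = as.character(band_ids)),
            class = "band_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.band_table <- function(x, ...) {
  cat(sprintf("DGGE band table: %d lanes x %d bands\n",
              nrow(x$intensities), ncol(x$intensities)))
  invisible(x)
}

#' Relative band intensities of one lane
#'
#' Drops zero-intensity bands and normalises the rest to proportions
#' \eqn{P_i = I_i / \sum_j I_j}.
#'
#' @param intensities numeric vector of band intensities, at least one
#'   positive.
#' @return A probability vector over the positive bands (sums to 1).
#' @examples
#' relative_intensities(c(1, 0, 3))  # 0.25 0.75
#' @export
relative_intensities <- function(intensities) {
  if (!is.numeric(intensities) || any(is.na(intensities)) || any(intensities < 0))
    stop("intensities must be non-negative numbers", call. = FALSE)
  pos <- intensities[intensities > 0]
  if (length(pos) == 0L)
    stop("empty lane: no positive band intensities", call. = FALSE)
  pos / sum(pos)
}

#' Shannon-Wiener diversity index
#'
#' \deqn{H' = -\sum_i P_i \ln P_i} over a probability vector of relative
#' band intensities (natural logarithm). A single band gives 0; `n` equally
#' intense bands give \eqn{\ln n}.
#'
#' @param p probability vector: positive entries summing to 1.
#' @return The index \eqn{H'} (dimensionless, >= 0).
#' @examples
#' shannon_index(c(0.5, 0.5))        # log(2)
#' shannon_index(c(0.5, 0.3, 0.2))   # 1.0297
#' @export
shannon_index <- function(p) {
  if (!is.numeric(p) || length(p) == 0L || any(is.na(p)) || any(p <= 0))
    stop("`p` must be a vector of positive probabilities", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-8)
    stop("`p` must sum to 1 (got ", format(sum(p)), ")", call. = FALSE)
  -sum(p * log(p))
}

#' Per-lane diversity of a band table
#'
#' Computes the number of positive bands and the Shannon-Wiener index for
#' every lane, in input order.
#'
#' @param table a [band_table()].
#' @return A data frame with columns `lane_id`, `n_bands`, `shannon`.
#' @export
diversity_table <- function(table) {
  stopifnot(inherits(table, "band_table"))
  rows <- lapply(seq_along(table$lane_ids), function(i) {
    x <- table$intensities[i, ]
    p <- tryCatch(relative_intensities(x), error = function(e)
      stop("lane '", table$lane_ids[i], "': ", conditionMessage(e), call. = FALSE))
    data.frame(lane_id = table$lane_ids[i], n_bands = length(p),
               shannon = shannon_index(p))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic DGGE gel
#'
#' Draws each lane's band-intensity profile from a symmetric Dirichlet
#' distribution (realised as normalised gamma draws) and scales it to
#' arbitrary intensity units. Smaller `concentration_parameter` concentrates
#' intensity on few bands, lowering the expected Shannon index; large values
#' approach the uniform profile with \eqn{H' \to \ln(n\_bands)}.
#'
#' @param n_lanes number of lanes.
#' @param n_bands number of bands per lane.
#' @param concentration_parameter positive Dirichlet concentration.
#' @param rng_seed integer seed for reproducibility.
#' @param intensity_scale total intensity per lane in arbitrary units.
#' @return A [band_table()].
#' @export
generate_synthetic_gel <- function(n_lanes, n_bands,
                                   concentration_parameter = 1,
                                   rng_seed,
                                   intensity_scale = 1000) {
  if (n_lanes < 1L || n_bands < 1L)
    stop("`n_lanes` and `n_bands` must be at least 1", call. = FALSE)
  if (concentration_parameter <= 0)
    stop("`concentration_parameter` must be positive", call. = FALSE)
  draws <- withr::with_seed(rng_seed, {
    g <- matrix(stats::rgamma(n_lanes * n_bands, shape = concentration_parameter),
                nrow = n_lanes)
    g / rowSums(g) * intensity_scale
  })
  band_table(draws, lane_ids = paste0("lane", seq_len(n_lanes)))
}
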