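#' Pair d0/d4 isotope doublets in a peak list
#'
#' Scans for peak pairs whose mass difference matches the expected
#' light/heavy spacing (4.0251 Da for d4/d0 linkers). Pairing is greedy on
#' descending light-peak intensity with single-use peaks, which is
#' deterministic and mirrors manual doublet picking: once a peak is consumed
#' as the heavy partner of an intense doublet it cannot seed another pair.
#'
#' @param peaks Data frame with `mass` and `intensity` columns.
#' @param expected_delta Heavy-minus-light spacing in Da (default: the
#'   d4/d0 bridge difference of the built-in linkers).
#' @param ppm_tol Allowed deviation of the observed spacing, expressed in
#'   ppm of the light mass (default 10).
#' @return Data frame with columns `light_mass`, `light_intensity`,
#'   `heavy_mass`, `heavy_intensity`, `delta`; zero rows when no doublet is
#'   found.
#' @export
pair_doublets <- function(peaks, expected_delta = doublet_delta(xl_linkers()$DSS),
                          ppm_tol = 10) {
  stopifnot(!is.null(peaks$intensity))
  n <- nrow(peaks)
  used <- logical(n)
  out <- list()
  order_light <- order(-peaks$intensity, peaks$mass)
  for (i in order_light) {
    if (used[i]) next
    tol <- ppm_tol * 1e-6 * peaks$mass[i]
    dev <- abs((peaks$mass - peaks$mass[i]) - expected_delta)
    cand <- which(!used & dev <= tol)
    cand <- setdiff(cand, i)
    if (length(cand) == 0) next
    j <- cand[which.min(dev[cand])]
    used[i] <- used[j] <- TRUE
    out[[length(out) + 1L]] <- data.frame(
      light_mass = peaks$mass[i], light_intensity = peaks$intensity[i],
      heavy_mass = peaks$mass[j], heavy_intensity = peaks$intensity[j],
      delta = peaks$mass[j] - peaks$mass[i]
    )
  }
  if (length(out) == 0) {
    return(data.frame(light_mass = numeric(0), light_intensity = numeric(0),
                      heavy_mass = numeric(0), heavy_intensity = numeric(0),
                      delta = numeric(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$light_mass), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Quantify identified conjugates from a doublet peak list
#'
#' Targeted companion to [pair_doublets()]: instead of scanning for any
#' 4-Da-spaced pair, each identified conjugate's light and heavy masses are
#' looked up in the peak list directly (closest peak within the ppm
#' tolerance per channel). This is the quantification route once
#' identifications exist, and it is immune to accidental spacing matches
#' among unrelated peaks.
#'
#' @param peaks Data frame with `mass` and `intensity` columns.
#' @param conjugates Data frame with `mass_light` and `mass_heavy` columns
#'   (any further columns, e.g. conjugate labels, are carried through).
#' @param ppm_tol Per-channel match tolerance in ppm.
#' @return The conjugate rows found in both channels, with `light_mass`,
#'   `light_intensity`, `heavy_mass`, `heavy_intensity` and `delta`
#'   columns appended (partition-ready).
#' @export
quantify_conjugates <- function(peaks, conjugates, ppm_tol = 5) {
  stopifnot(!is.null(peaks$intensity), ppm_tol > 0)
  rows <- list()
  for (i in seq_len(nrow(conjugates))) {
    find <- function(m) {
      hits <- which(abs(peaks$mass - m) / m * 1e6 <= ppm_tol)
      if (length(hits) == 0) return(NA_integer_)
      hits[which.min(abs(peaks$mass[hits] - m))]
    }
    pl <- find(conjugates$mass_light[i])
    ph <- find(conjugates$mass_heavy[i])
    if (is.na(pl) || is.na(ph)) next
    r <- conjugates[i, , drop = FALSE]
    r$light_mass <- peaks$mass[pl]
    r$light_intensity <- peaks$intensity[pl]
    r$heavy_mass <- peaks$mass[ph]
    r$heavy_intensity <- peaks$intensity[ph]
    r$delta <- r$heavy_mass - r$light_mass
    rows[[length(rows) + 1L]] <- r
  }
  if (length(rows) == 0) {
    out <- conjugates[0, , drop = FALSE]
    out$light_mass <- out$light_intensity <- numeric(0)
    out$heavy_mass <- out$heavy_intensity <- out$delta <- numeric(0)
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Partition a doublet into light/heavy percentages
#'
#' `%light = I_L / (I_L + I_H) * 100`, with `%heavy` its exact complement.
#' When the light channel carries the unbound state and the heavy channel
#' the DNA-bound state, `%light` is the incidence of the conjugate in the
#' free form.
#'
#' @param pairs Doublet table from [pair_doublets()] (columns
#'   `light_intensity`, `heavy_intensity`), or a single pair as a 2-vector
#'   `c(light, heavy)`.
#' @return The table with added `pct_light` and `pct_heavy` columns summing
#'   to 100 per row.
#' @examples
#' partition(c(959, 41)) # 95.9 / 4.1
#' @export
partition <- function(pairs) {
  if (is.numeric(pairs) && length(pairs) == 2) {
    pairs <- data.frame(light_intensity = pairs[1], heavy_intensity = pairs[2])
  }
  tot <- pairs$light_intensity + pairs$heavy_intensity
  if (any(tot <= 0)) stop("doublet with zero total intensity cannot be partitioned")
  pairs$pct_light <- pairs$light_intensity / tot * 100
  pairs$pct_heavy <- 100 - pairs$pct_light
  pairs
}

#' Aggregate partition percentages over replicates
#'
#' @param rows Data frame with columns `conjugate`, `linker`, `replicate`,
#'   `pct_light` (one row per replicate measurement).
#' @return One row per conjugate and linker with `mean_pct_light`,
#'   `sd_pct_light` (sample sd; 0 with `single_replicate = TRUE` when only
#'   one replicate exists) and `n_replicates`.
#' @export
aggregate_replicates <- function(rows) {
  stopifnot(nrow(rows) >= 1)
  key <- interaction(rows$conjugate, rows$linker, drop = TRUE)
  out <- lapply(split(rows, key), function(g) {
    data.frame(conjugate = g$conjugate[1], linker = g$linker[1],
               mean_pct_light = mean(g$pct_light),
               sd_pct_light = if (nrow(g) > 1) stats::sd(g$pct_light) else 0,
               n_replicates = nrow(g),
               single_replicate = nrow(g) == 1,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$linker, res$conjugate), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Binding-induced change in cross-link incidence
#'
#' For each conjugate and linker length, computes the drop in incidence
#' between the free-state channel and the bound-state channel of the mixed
#' 1:1 sample: `delta = %free - %bound`. Conjugates whose incidence drops on
#' binding are labelled `inhibited`, those that rise `enhanced`, and
#' `|delta|` below the threshold `unchanged`.
#'
#' @param partitions Aggregated table from [aggregate_replicates()], with
#'   `mean_pct_light` carrying the free-state percentage.
#' @param threshold Absolute `delta` (%) below which a conjugate is called
#'   unchanged (default 10).
#' @return The table with added `pct_free`, `pct_bound`, `delta` and
#'   `direction` columns.
#' @export
differential_report <- function(partitions, threshold = 10) {
  partitions$pct_free <- partitions$mean_pct_light
  partitions$pct_bound <- 100 - partitions$mean_pct_light
  partitions$delta <- partitions$pct_free - partitions$pct_bound
  partitions$direction <- ifelse(
    abs(partitions$delta) < threshold, "unchanged",
    ifelse(partitions$delta > 0, "inhibited", "enhanced")
  )
  partitions
}
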