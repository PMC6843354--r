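#' Number of exchangeable backbone amide hydrogens
#'
#' The N-terminal residue's amide proton back-exchanges too fast to be
#' observed and proline has no amide hydrogen, so
#' `N_ex = length - 1 - (prolines at positions 2..end)`. The common
#' alternative convention that also discounts the second residue is
#' available via `rule = "skip_first_two"`.
#'
#' @param sequence Peptide sequence.
#' @param rule `"skip_first"` (default) or `"skip_first_two"`.
#' @return Integer count (>= 0); length-1 peptides return 0 with a warning.
#' @examples
#' exchangeable_count("AGPLK") # 3
#' @export
exchangeable_count <- function(sequence, rule = c("skip_first", "skip_first_two")) {
  rule <- match.arg(rule)
  if (nchar(sequence) == 0) stop("peptide must be non-empty")
  res <- strsplit(sequence, "")[[1]]
  skip <- if (rule == "skip_first") 1L else 2L
  if (length(res) <= skip) {
    warning("peptide '", sequence, "' has no observable exchangeable amides")
    return(0L)
  }
  tail_res <- res[(skip + 1L):length(res)]
  as.integer(length(tail_res) - sum(tail_res == "P"))
}

# residue positions whose amide contributes to a peptide's uptake
# (construct numbering): skip the peptide's first residue(s) and prolines
covered_residues <- function(sequence, start, rule = "skip_first") {
  res <- strsplit(sequence, "")[[1]]
  skip <- if (rule == "skip_first") 1L else 2L
  if (length(res) <= skip) return(integer(0))
  idx <- (skip + 1L):length(res)
  idx <- idx[res[idx] != "P"]
  start + idx - 1L
}

#' Relative deuteration of a peptide
#'
#' `DR = (m_t - m_0) / N_ex`, clamped to the physical range; the number of
#' clamping events is attached as an attribute so that systematic drift is
#' visible.
#'
#' @param m_t Centroid mass at the exchange timepoint (Da); vectorized.
#' @param m_0 Undeuterated reference centroid (Da).
#' @param n_ex Exchangeable amide count from [exchangeable_count()]
#'   (must be >= 1).
#' @return Numeric DR in `[0, 1]` with attribute `n_clamped`.
#' @examples
#' relative_uptake(1003, 1000, 6) # 0.5
#' @export
relative_uptake <- function(m_t, m_0, n_ex) {
  if (any(n_ex < 1)) stop("n_ex must be >= 1 for relative uptake")
  dr <- (m_t - m_0) / n_ex
  clamped <- sum(dr < 0 | dr > 1)
  dr <- pmin(pmax(dr, 0), 1)
  attr(dr, "n_clamped") <- clamped
  dr
}

#' Per-peptide deuterium uptake from a centroid table
#'
#' Each peptide/state/replicate series must include a `time == 0`
#' undeuterated reference row; uptake is the centroid excess over that
#' reference, and DR its ratio to the exchangeable amide count.
#'
#' @param centroids Data frame with columns `sequence`, `start`, `end`,
#'   `state`, `time` (min), `replicate`, `centroid` (Da).
#' @param rule Exchangeable-amide rule, see [exchangeable_count()].
#' @return Data frame of the non-zero timepoints with added `n_ex`,
#'   `uptake` (Da) and `dr` columns; clamp count in `attr(, "n_clamped")`.
#' @export
peptide_uptake <- function(centroids, rule = "skip_first") {
  key <- with(centroids, paste(sequence, start, state, replicate, sep = "\r"))
  ref <- centroids[centroids$time == 0, , drop = FALSE]
  if (nrow(ref) == 0) stop("centroid table has no time == 0 reference rows")
  ref_key <- with(ref, paste(sequence, start, state, replicate, sep = "\r"))
  m0 <- ref$centroid[match(key, ref_key)]
  if (any(is.na(m0))) {
    miss <- unique(centroids$sequence[is.na(m0)])
    stop("missing time-0 reference for peptide(s): ", paste(miss, collapse = ", "))
  }
  out <- centroids[centroids$time > 0, , drop = FALSE]
  m0 <- m0[centroids$time > 0]
  out$n_ex <- vapply(out$sequence, exchangeable_count, integer(1),
                     rule = rule, USE.NAMES = FALSE)
  if (any(out$n_ex < 1)) stop("peptide with no exchangeable amides in table")
  out$uptake <- out$centroid - m0
  dr <- relative_uptake(out$centroid, m0, out$n_ex)
  out$dr <- as.numeric(dr)
  rownames(out) <- NULL
  attr(out, "n_clamped") <- attr(dr, "n_clamped")
  out
}

#' Consolidate overlapping peptide uptakes to segment/residue level
#'
#' Deterministic shortest-fragment subtraction: the covered residue sets of
#' all peptides define atomic segments; peptides are processed from
#' shortest to longest, and each peptide's uptake not yet explained by
#' previously assigned segments is attributed to its unassigned segments
#' (spread in proportion to their exchangeable-amide counts). Residues
#' inside an unresolved segment share its DR. A least-squares mode solves
#' the same segment system globally; both agree on fully determined
#' noiseless systems.
#'
#' @param peptide_tab Data frame for one state and timepoint: columns
#'   `sequence`, `start`, `end`, `uptake` (Da, replicate-averaged or single
#'   replicate).
#' @param protein Protein sequence (construct); peptide positions are
#'   validated against it before consolidation.
#' @param start_pos Construct-numbering position of the first protein
#'   residue.
#' @param method `"subtraction"` (default) or `"least_squares"`.
#' @param rule Exchangeable-amide rule.
#' @param tol Negative-uptake tolerance before a segment is clamped to 0
#'   and flagged.
#' @return List with `segments` (seg_start, seg_end, uptake, n_ex, dr),
#'   `residues` (residue, dr; prolines and never-covered residues absent),
#'   `residuals` (per-peptide unexplained uptake) and `n_clamped`.
#' @export
residue_consolidation <- function(peptide_tab, protein, start_pos = 1L,
                                  method = c("subtraction", "least_squares"),
                                  rule = "skip_first", tol = 1e-6) {
  method <- match.arg(method)
  np <- nrow(peptide_tab)
  for (i in seq_len(np)) {
    ref <- substr(protein, peptide_tab$start[i] - start_pos + 1L,
                  peptide_tab$end[i] - start_pos + 1L)
    if (ref != peptide_tab$sequence[i]) {
      stop("peptide ", peptide_tab$sequence[i], " (", peptide_tab$start[i],
           "-", peptide_tab$end[i], ") does not match the construct sequence")
    }
  }
  cov <- lapply(seq_len(np), function(i) {
    covered_residues(peptide_tab$sequence[i], peptide_tab$start[i], rule)
  })
  all_res <- sort(unique(unlist(cov)))
  if (length(all_res) == 0) stop("no covered residues in peptide table")
  # atomic segments: maximal runs of residues sharing the same covering set
  memb <- vapply(cov, function(cr) all_res %in% cr, logical(length(all_res)))
  if (length(all_res) == 1) memb <- matrix(memb, nrow = 1)
  sig <- apply(memb, 1, paste, collapse = "")
  breaks <- c(TRUE, sig[-1] != sig[-length(sig)] |
                diff(all_res) != 1)
  seg_id <- cumsum(breaks)
  nseg <- max(seg_id)
  seg_start <- tapply(all_res, seg_id, min)
  seg_end <- tapply(all_res, seg_id, max)
  seg_nex <- tapply(all_res, seg_id, length)  # covered residues are amide-bearing
  seg_in_pep <- lapply(seq_len(np), function(i) unique(seg_id[memb[, i]]))

  seg_uptake <- rep(NA_real_, nseg)
  n_clamped <- 0L
  residuals <- numeric(np)
  ord <- order(peptide_tab$end - peptide_tab$start, peptide_tab$start)

  if (method == "subtraction") {
    for (i in ord) {
      segs <- seg_in_pep[[i]]
      assigned <- segs[!is.na(seg_uptake[segs])]
      unassigned <- segs[is.na(seg_uptake[segs])]
      rem <- peptide_tab$uptake[i] - sum(seg_uptake[assigned])
      if (length(unassigned) == 0) {
        residuals[i] <- rem
        next
      }
      if (rem < -tol) {
        n_clamped <- n_clamped + 1L
        rem <- 0
      }
      rem <- max(rem, 0)
      w <- seg_nex[unassigned] / sum(seg_nex[unassigned])
      seg_uptake[unassigned] <- rem * w
    }
  } else {
    A <- t(memb * 1)             # peptides x residues
    # collapse residues to segments
    M <- matrix(0, np, nseg)
    for (s in seq_len(nseg)) {
      M[, s] <- rowSums(A[, seg_id == s, drop = FALSE]) / sum(seg_id == s)
    }
    # segment uptake per exchangeable amide, minimum-norm least squares
    X <- M * matrix(seg_nex, np, nseg, byrow = TRUE)
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-10
    coef <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% peptide_tab$uptake) / sv$d[pos])
    x <- as.numeric(coef) * seg_nex
    n_clamped <- sum(x < -tol)
    seg_uptake <- pmax(x, 0)
    residuals <- as.numeric(peptide_tab$uptake -
                              (M * matrix(seg_nex, np, nseg, byrow = TRUE)) %*%
                              (seg_uptake / seg_nex))
  }

  seg_dr <- pmin(pmax(seg_uptake / seg_nex, 0), 1)
  segments <- data.frame(seg_start = as.integer(seg_start),
                         seg_end = as.integer(seg_end),
                         uptake = as.numeric(seg_uptake),
                         n_ex = as.integer(seg_nex),
                         dr = as.numeric(seg_dr))
  res_rows <- data.frame(residue = all_res, dr = seg_dr[seg_id])
  list(segments = segments, residues = res_rows,
       residuals = data.frame(sequence = peptide_tab$sequence,
                              start = peptide_tab$start,
                              residual = residuals),
       n_clamped = n_clamped)
}

#' Residue-level DR table across states, timepoints and replicates
#'
#' Runs [residue_consolidation()] independently for every state, timepoint
#' and replicate of an uptake table, then averages over replicates.
#'
#' @param uptake_tab Output of [peptide_uptake()].
#' @param protein Protein sequence.
#' @param start_pos Construct numbering of the first residue.
#' @param method,rule Passed to [residue_consolidation()].
#' @return Data frame `residue`, `state`, `time`, `dr` (replicate mean),
#'   `sd` (replicate sd, 0 for a single replicate), `n`.
#' @export
residue_dr_table <- function(uptake_tab, protein, start_pos = 1L,
                             method = "subtraction", rule = "skip_first") {
  cells <- unique(uptake_tab[, c("state", "time", "replicate")])
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- uptake_tab$state == cells$state[i] &
      uptake_tab$time == cells$time[i] &
      uptake_tab$replicate == cells$replicate[i]
    cons <- residue_consolidation(uptake_tab[sel, , drop = FALSE], protein,
                                  start_pos, method = method, rule = rule)
    r <- cons$residues
    r$state <- cells$state[i]; r$time <- cells$time[i]
    r$replicate <- cells$replicate[i]
    rows[[length(rows) + 1L]] <- r
  }
  long <- do.call(rbind, rows)
  key <- interaction(long$residue, long$state, long$time, drop = TRUE)
  agg <- lapply(split(long, key), function(g) {
    data.frame(residue = g$residue[1], state = g$state[1], time = g$time[1],
               dr = mean(g$dr), sd = if (nrow(g) > 1) stats::sd(g$dr) else 0,
               n = nrow(g), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, agg)
  res <- res[order(res$state, res$time, res$residue), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Differential deuteration profile between free and complexed states
#'
#' `dDR = DR(free) - DR(complex)` on a matched residue x timepoint grid;
#' positive values mean protection upon binding. A difference is flagged
#' significant when `|dDR| > k * sd_diff`, where `sd_diff` combines the
#' replicate standard deviations of the two states.
#'
#' @param free,complex Residue DR tables from [residue_dr_table()] (one
#'   state each).
#' @param k Significance multiplier (default 2).
#' @return Data frame `residue`, `time`, `ddr`, `sd_diff`, `significant`.
#' @export
hdx_differential <- function(free, complex, k = 2) {
  kf <- paste(free$residue, free$time)
  kc <- paste(complex$residue, complex$time)
  miss <- c(setdiff(kf, kc), setdiff(kc, kf))
  if (length(miss) > 0) {
    stop("residue/timepoint grids do not match; missing cells: ",
         paste(utils::head(miss, 10), collapse = "; "),
         if (length(miss) > 10) " ..." else "")
  }
  complex <- complex[match(kf, kc), , drop = FALSE]
  ddr <- free$dr - complex$dr
  ddr[abs(ddr) < 1e-9] <- 0   # numerical floor: consolidation round-off
  out <- data.frame(residue = free$residue, time = free$time,
                    ddr = ddr,
                    sd_diff = sqrt(free$sd^2 + complex$sd^2))
  out$significant <- abs(out$ddr) > k * out$sd_diff
  out <- out[order(out$time, out$residue), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify the time course of a differential-protection region
#'
#' Distinguishes protection that builds up and saturates from transient
#' protection that rises and then returns towards initial levels, using the
#' sign pattern of successive differences with a noise tolerance.
#'
#' @param values Numeric dDR series over >= 4 timepoints (time-ordered).
#' @param noise Noise band; values and differences within it are treated as
#'   zero (default 0.05).
#' @return One of `"flat"`, `"rising-saturating"`, `"rise-then-fall"`,
#'   `"other"`.
#' @examples
#' classify_time_course(c(0.05, 0.15, 0.30, 0.38, 0.40, 0.40))
#' classify_time_course(c(0.05, 0.35, 0.40, 0.20, 0.08, 0.05))
#' @export
classify_time_course <- function(values, noise = 0.05) {
  if (length(values) < 4) stop("need at least 4 timepoints to classify")
  if (all(abs(values) <= noise)) return("flat")
  d <- diff(values)
  imax <- which.max(values)
  rises_to_max <- all(d[seq_len(imax - 1)] >= -noise)
  falls_after <- imax < length(values) && all(d[imax:(length(d))] <= noise)
  returns <- values[length(values)] <= max(values) / 2 ||
    values[length(values)] <= noise
  if (rises_to_max && falls_after && returns) return("rise-then-fall")
  if (all(d >= -noise)) return("rising-saturating")
  "other"
}

#' Export docking-active residues
#'
#' Residues showing significant positive protection (`dDR > 0`) at one or
#' more timepoints, i.e. reduced exchange upon binding, emitted as the
#' active-residue list a docking run consumes.
#'
#' @param profile Differential table from [hdx_differential()].
#' @param threshold Optional minimum dDR a residue must reach (applied on
#'   top of the significance flag).
#' @param path Optional output file (one residue number per line).
#' @return Sorted integer vector of residue positions.
#' @export
export_active_residues <- function(profile, threshold = 0, path = NULL) {
  sel <- profile$significant & profile$ddr > 0 & profile$ddr >= threshold
  res <- sort(unique(profile$residue[sel]))
  if (!is.null(path)) writeLines(as.character(res), path)
  res
}
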