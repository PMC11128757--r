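# Region-level attention scoring and rank correlation with semi-quantitative
# neuropathology grades. The AD-channel attention map is resampled to the
# parcellation grid (trilinear), aggregated per region as a volume-normalized
# sum (i.e. the regional mean), and correlated across subjects with 0-3
# ordinal grades of amyloid-beta deposits, neurofibrillary tangles (NFT) and
# neuritic plaques (NP) via Spearman's rank correlation; p-values are
# unadjusted for multiple comparisons.

#' Region-level attention scores
#'
#' Sums attention over each parcellation region and divides by the region's
#' voxel count. The background (label 0) is excluded. If the attention grid
#' is at a different resolution than the parcellation it is first resampled
#' trilinearly.
#'
#' @param attention_channel 3D array (one attention channel).
#' @param parcellation a `dg_parcellation`.
#' @return data frame with `region_id`, `region_name`, `attention_sum`,
#'   `voxel_count`, `score`.
#' @export
region_scores <- function(attention_channel, parcellation) {
  stopifnot(inherits(parcellation, "dg_parcellation"))
  if (!identical(dim(attention_channel), dim(parcellation$labels))) {
    attention_channel <- resample_trilinear(attention_channel,
                                            dim(parcellation$labels))
  }
  ids <- sort(unique(as.vector(parcellation$labels)))
  ids <- ids[ids > 0L]
  counts <- vapply(ids, function(r) sum(parcellation$labels == r), numeric(1))
  if (any(counts < 1)) stop("parcellation contains an empty region", call. = FALSE)
  sums <- vapply(ids, function(r) sum(attention_channel[parcellation$labels == r]),
                 numeric(1))
  data.frame(region_id = ids,
             region_name = unname(parcellation$region_names[as.character(ids)]),
             attention_sum = sums, voxel_count = as.integer(counts),
             score = sums / counts)
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' rho is the Pearson correlation of the average-ranked vectors (the standard
#' tie treatment); the two-sided p-value uses the t-approximation with n - 2
#' degrees of freedom and is not adjusted for multiple comparisons. For small
#' samples (`n <= 10`) an exact permutation p-value can be requested as a
#' cross-check.
#'
#' @param x,y numeric vectors of equal length `n >= 3`; ties allowed.
#' @param exact if `TRUE` and `n <= 10`, compute the permutation p-value by
#'   full enumeration instead of the t-approximation.
#' @return list with `rho`, `p`, `n`, and `reason` (`NA` rho when either
#'   vector has zero variance).
#' @export
spearman_rank <- function(x, y, exact = FALSE) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n,
                reason = "zero variance in x or y"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (exact && n <= 10L) {
    perms <- permutations_of(n)
    obs <- abs(rho)
    cnt <- 0L
    for (i in seq_len(nrow(perms))) {
      if (abs(stats::cor(rx, ry[perms[i, ]])) >= obs - 1e-12) cnt <- cnt + 1L
    }
    p <- cnt / nrow(perms)
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n, reason = NA_character_)
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(v) {
    cbind(v, sub + (sub >= v))   # permutations starting with value v
  }))
}

#' Region x stain correlation table
#'
#' For every (region, stain) pair, Spearman-correlates region attention
#' scores with pathology grades across the subjects present in both tables.
#' Cells with fewer than 3 shared subjects are kept but marked missing.
#'
#' @param scores data frame with `subject_id`, `region_id`, `score` (one row
#'   per subject x region; see [region_scores()]).
#' @param grades data frame with `subject_id`, `region_id`, `stain`,
#'   `grade`.
#' @return data frame with one row per (region, stain): `region_id`,
#'   `stain`, `rho`, `p`, `n`, `missing`.
#' @export
correlation_table <- function(scores, grades) {
  need <- c("subject_id", "region_id", "score")
  if (!all(need %in% names(scores))) {
    stop("scores must have columns subject_id, region_id, score", call. = FALSE)
  }
  need <- c("subject_id", "region_id", "stain", "grade")
  if (!all(need %in% names(grades))) {
    stop("grades must have columns subject_id, region_id, stain, grade", call. = FALSE)
  }
  regions <- sort(unique(grades$region_id))
  stains <- unique(grades$stain)
  rows <- list()
  for (r in regions) {
    sc <- scores[scores$region_id == r, ]
    for (st in stains) {
      gr <- grades[grades$region_id == r & grades$stain == st, ]
      m <- merge(sc[, c("subject_id", "score")],
                 gr[, c("subject_id", "grade")], by = "subject_id")
      if (nrow(m) < 3L) {
        rows[[length(rows) + 1L]] <- data.frame(
          region_id = r, stain = st, rho = NA_real_, p = NA_real_,
          n = nrow(m), missing = TRUE)
        next
      }
      sp <- spearman_rank(m$score, m$grade)
      rows[[length(rows) + 1L]] <- data.frame(
        region_id = r, stain = st, rho = sp$rho, p = sp$p, n = sp$n,
        missing = is.na(sp$rho))
    }
  }
  do.call(rbind, rows)
}

#' Share of attention mass inside designated regions
#'
#' Fraction of the total attention (over non-background voxels, after
#' resampling to the parcellation grid) that falls inside the given regions.
#' Used to quantify whether prior supervision concentrates attention on
#' disease regions; as a share it is invariant to the overall gain of the
#' sigmoid gates.
#'
#' @param attention_channel 3D array (one attention channel).
#' @param parcellation a `dg_parcellation`.
#' @param regions integer region ids.
#' @return scalar in `[0, 1]`.
#' @export
attention_mass_share <- function(attention_channel, parcellation, regions) {
  if (!identical(dim(attention_channel), dim(parcellation$labels))) {
    attention_channel <- resample_trilinear(attention_channel,
                                            dim(parcellation$labels))
  }
  lab <- parcellation$labels
  total <- sum(attention_channel[lab > 0L])
  if (total <= 0) return(NA_real_)
  sum(attention_channel[lab %in% regions]) / total
}
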