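# Delta SNP-index bulked-segregant mapping: per-SNP indices, sliding
# window smoothing, simulation-based null confidence bands, and candidate
# interval calls. Sign convention: delta = index(high / trait-mutant bulk)
# - index(low / wild-phenotype bulk), with the mutant-parent allele as alt.

#' Per-SNP SNP-index and delta
#'
#' SNP-index = alt / (alt + ref) per bulk; delta = index_high - index_low.
#' SNPs with total depth below `min_depth` in either bulk (including
#' zero-depth SNPs) are dropped; the number dropped is recorded in
#' `attr(, "n_dropped")`.
#'
#' @param counts data.frame as from [gen_bsa_counts()] /
#'   [read_bsa_counts()].
#' @param min_depth minimum per-bulk depth to keep a SNP (default 10).
#' @return data.frame (`chrom`, `pos`, `depth_high`, `depth_low`,
#'   `index_high`, `index_low`, `delta`), sorted by chrom then pos.
#' @export
compute_delta_index <- function(counts, min_depth = 10L) {
  dh <- counts$ref_depth_high + counts$alt_depth_high
  dl <- counts$ref_depth_low + counts$alt_depth_low
  keep <- dh >= min_depth & dl >= min_depth
  out <- data.frame(
    chrom = counts$chrom[keep], pos = counts$pos[keep],
    depth_high = dh[keep], depth_low = dl[keep],
    index_high = counts$alt_depth_high[keep] / dh[keep],
    index_low = counts$alt_depth_low[keep] / dl[keep],
    stringsAsFactors = FALSE)
  out$delta <- out$index_high - out$index_low
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Sliding-window smoothing of a delta SNP-index profile
#'
#' Unweighted mean of per-SNP deltas in windows of `window` bp advanced by
#' `step` bp along each chromosome (from position 1 to the last SNP).
#' Windows with no SNPs are emitted with `n_snps = 0` and `NA` delta.
#'
#' @param snp_table output of [compute_delta_index()].
#' @param window window size in bp.
#' @param step step size in bp (`window >= step > 0`).
#' @return data.frame (`chrom`, `window_start`, `window_end`,
#'   `mean_index_high`, `mean_index_low`, `delta`, `n_snps`,
#'   `mean_depth`).
#' @export
smooth_profile <- function(snp_table, window = 2e6, step = 5e4) {
  if (!(window >= step && step > 0)) stop("need window >= step > 0")
  out <- lapply(split(snp_table, snp_table$chrom), function(tab) {
    tab <- tab[order(tab$pos), , drop = FALSE]
    L <- max(tab$pos)
    starts <- seq(1, max(1, L - window + 1), by = step)
    # cumulative sums for O(1) window means
    cs_d <- c(0, cumsum(tab$delta))
    cs_h <- c(0, cumsum(tab$index_high))
    cs_l <- c(0, cumsum(tab$index_low))
    cs_dp <- c(0, cumsum((tab$depth_high + tab$depth_low) / 2))
    i0 <- findInterval(starts - 1, tab$pos)       # SNPs strictly before
    i1 <- findInterval(starts + window - 1, tab$pos) # SNPs inside or before
    n <- i1 - i0
    mean_of <- function(cs) ifelse(n > 0, (cs[i1 + 1] - cs[i0 + 1]) / n, NA)
    data.frame(chrom = tab$chrom[1], window_start = starts,
               window_end = starts + window - 1,
               mean_index_high = mean_of(cs_h),
               mean_index_low = mean_of(cs_l),
               delta = mean_of(cs_d), n_snps = n,
               mean_depth = mean_of(cs_dp), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Simulation-based null confidence band for delta SNP-index
#'
#' Simulates unselected F2 bulks (bulk allele frequency from `n_high` /
#' `n_low` individuals drawn 1:2:1, binomial read sampling at each depth)
#' and records the (alpha/2, 1 - alpha/2) quantiles of the null per-SNP
#' delta, as a function of depth.
#'
#' @param depths depths at which to tabulate the band.
#' @param n_high,n_low bulk sizes (individuals).
#' @param n_sim simulation replicates per depth (>= 1000).
#' @param alpha two-sided band level (e.g. 0.01).
#' @param seed integer seed.
#' @return object of class `bsa_null_ci`: data.frame (`depth`, `ci_low`,
#'   `ci_high`) with `alpha`, `n_sim` attributes; query with
#'   [ci_at_depth()].
#' @export
null_ci <- function(depths = c(10, 20, 50, 100, 200), n_high = 20L,
                    n_low = 20L, n_sim = 10000L, alpha = 0.01,
                    seed = 1L) {
  if (n_sim < 1000L) stop("n_sim must be >= 1000")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  with_seed(seed, {
    rows <- lapply(sort(unique(depths)), function(dp) {
      p_h <- stats::rbinom(n_sim, 2L * n_high, 0.5) / (2L * n_high)
      p_l <- stats::rbinom(n_sim, 2L * n_low, 0.5) / (2L * n_low)
      delta <- stats::rbinom(n_sim, dp, p_h) / dp -
        stats::rbinom(n_sim, dp, p_l) / dp
      q <- stats::quantile(delta, c(alpha / 2, 1 - alpha / 2),
                           names = FALSE, type = 1)
      data.frame(depth = dp, ci_low = q[1], ci_high = q[2])
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    structure(out, class = c("bsa_null_ci", "data.frame"), alpha = alpha,
              n_sim = as.integer(n_sim))
  })
}

#' Interpolate a null band at given depths
#' @param ci a `bsa_null_ci` from [null_ci()].
#' @param depth numeric vector of depths.
#' @return data.frame (`ci_low`, `ci_high`) of the band at each depth.
#' @export
ci_at_depth <- function(ci, depth) {
  lo <- stats::approx(ci$depth, ci$ci_low, xout = depth, rule = 2)$y
  hi <- stats::approx(ci$depth, ci$ci_high, xout = depth, rule = 2)$y
  data.frame(ci_low = lo, ci_high = hi)
}

#' Call candidate intervals from a smoothed profile
#'
#' Flags windows whose delta exceeds the depth-matched upper null band,
#' merges flagged runs separated by at most `merge_gap` windows, and
#' reports maximal runs of at least `min_run` windows as candidate
#' intervals with their peak.
#'
#' @param profile output of [smooth_profile()].
#' @param ci a `bsa_null_ci` at the same alpha as desired for the calls.
#' @param min_run minimum consecutive flagged windows (default 5).
#' @param merge_gap maximum unflagged gap (windows) merged into a run
#'   (default 2).
#' @return data.frame (`chrom`, `start`, `end`, `n_windows`, `peak_pos`,
#'   `peak_delta`), 0 rows when nothing exceeds the band.
#' @export
call_intervals <- function(profile, ci, min_run = 5L, merge_gap = 2L) {
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_windows = integer(0),
                      peak_pos = numeric(0), peak_delta = numeric(0))
  if (nrow(profile) == 0L) return(empty)
  band <- ci_at_depth(ci, ifelse(is.na(profile$mean_depth), Inf,
                                 profile$mean_depth))
  flag <- !is.na(profile$delta) & profile$delta > band$ci_high
  out <- empty
  for (ch in unique(profile$chrom)) {
    sel <- which(profile$chrom == ch)
    f <- flag[sel]
    idx <- which(f)
    if (length(idx) == 0L) next
    # merge flagged indices separated by <= merge_gap + 1
    brk <- c(0L, which(diff(idx) > merge_gap + 1L), length(idx))
    for (b in seq_len(length(brk) - 1L)) {
      run <- idx[(brk[b] + 1L):brk[b + 1L]]
      span <- run[1]:run[length(run)]
      if (length(span) < min_run) next
      rows <- sel[span]
      pk <- rows[which.max(profile$delta[rows])]
      out <- rbind(out, data.frame(
        chrom = ch, start = profile$window_start[rows[1]],
        end = profile$window_end[rows[length(rows)]],
        n_windows = length(span),
        peak_pos = (profile$window_start[pk] + profile$window_end[pk]) / 2,
        peak_delta = profile$delta[pk]))
    }
  }
  rownames(out) <- NULL
  out[order(-out$peak_delta), , drop = FALSE]
}
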