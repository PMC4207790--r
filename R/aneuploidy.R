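# Whole-chromosome duplication detection from read coverage: random fixed-
# size windows, per-window mean depth, and a per-chromosome median ratio
# against the rest of the genome. On a haploid background a duplicated
# chromosome sits near ratio 2.

#' Sample random coverage windows
#'
#' Draws `n_windows` windows of `window_size` bp genome-wide, allocated to
#' chromosomes proportionally to length with a floor of `min_per_chrom`
#' windows each, and records the mean depth of every window. Start positions
#' are uniform over valid starts (windows lie fully inside the chromosome).
#' Chromosomes shorter than `window_size` are excluded with a warning.
#'
#' @param track a `coverage_track` (strain_id, chrom, pos, depth)
#' @param window_size window width in bp (default 10000)
#' @param n_windows total windows (default 500)
#' @param min_per_chrom minimum windows per chromosome (default 20)
#' @param seed RNG seed
#' @return list of class `window_coverage`: `strain_id`, `windows`
#'   (data.table: chrom, start, mean_depth), `window_size`, `n_windows`
#' @export
sample_windows <- function(track, window_size = 10000L, n_windows = 500L,
                           min_per_chrom = 20L, seed = 1L) {
  window_size <- assert_count(window_size, "window_size")
  n_windows <- assert_count(n_windows, "n_windows")
  len <- vapply(split(track$pos, track$chrom), max, numeric(1))
  short <- names(len)[len < window_size]
  if (length(short)) {
    warning("chromosomes shorter than window_size excluded: ",
            paste(short, collapse = ", "))
    len <- len[!names(len) %in% short]
  }
  if (!length(len)) stop("no chromosome is long enough", call. = FALSE)
  alloc <- pmax(round(n_windows * len / sum(len)), min_per_chrom)
  depth_by <- split(track$depth, track$chrom)
  local_seed(seed, {
    win <- lapply(names(len), function(ch) {
      d <- depth_by[[ch]]
      starts <- sample.int(len[[ch]] - window_size + 1L, alloc[[ch]],
                           replace = TRUE)
      mu <- vapply(starts, function(s)
        mean(d[s:(s + window_size - 1L)]), numeric(1))
      data.table::data.table(chrom = ch, start = starts, mean_depth = mu)
    })
    structure(list(strain_id = track$strain_id[1],
                   windows = data.table::rbindlist(win),
                   window_size = window_size,
                   n_windows = sum(alloc)),
              class = "window_coverage")
  })
}

#' Call whole-chromosome duplications
#'
#' For each chromosome, ratio = median window depth of that chromosome
#' divided by the median window depth of all other chromosomes (the
#' chromosome under test never contributes to its own denominator). A
#' chromosome is called duplicated when the ratio falls inside `band`
#' (default [1.75, 2.25], targeting the 2x coverage of a duplication on a
#' haploid background). Medians make the call robust to focal outliers, and
#' the verdict is invariant to rescaling all depths.
#'
#' @param summary a `window_coverage` from [sample_windows()]
#' @param band duplication ratio band, length-2 numeric
#' @return data.table: strain_id, chrom, ratio, duplicated
#' @export
call_duplications <- function(summary, band = c(1.75, 2.25)) {
  w <- summary$windows
  chroms <- unique(w$chrom)
  if (length(chroms) < 2)
    stop("need at least two chromosomes to form a ratio", call. = FALSE)
  ratio <- vapply(chroms, function(ch) {
    num <- stats::median(w$mean_depth[w$chrom == ch])
    den <- stats::median(w$mean_depth[w$chrom != ch])
    if (den == 0) stop("zero median coverage outside ", ch, call. = FALSE)
    num / den
  }, numeric(1))
  data.table::data.table(strain_id = summary$strain_id,
                         chrom = chroms,
                         ratio = unname(ratio),
                         duplicated = ratio >= band[1] & ratio <= band[2])
}
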