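#' Nucleotide composition and strand-skew statistics
#'
#' AT content, AT skew and GC skew of a nucleotide sequence, computed on
#' the given (major) strand:
#' \deqn{AT\,skew = (A - T)/(A + T), \qquad GC\,skew = (G - C)/(G + C).}
#' `N` and any ambiguity characters are excluded from numerator and
#' denominator and tallied in `n_excluded`. When a denominator is zero
#' the corresponding skew is reported missing (`NA`), never `0`.
#'
#' @param sequence nucleotide string (or a [mito_genome()]).
#' @return list of class `CompositionStats`: `at_content`, `at_skew`,
#'   `gc_skew`, `counts` (named A,C,G,T,N tallies), `n_excluded`.
#' @examples
#' composition_stats("AAT")$at_skew   # 1/3
#' composition_stats("ATGC")$gc_skew  # 0
#' @export
composition_stats <- function(sequence) {
  if (inherits(sequence, "MitoGenome")) sequence <- sequence$sequence
  if (!nzchar(sequence)) stop("sequence must be non-empty")
  sequence <- toupper(sequence)
  ch <- seq_chars(sequence)
  counts <- c(A = sum(ch == "A"), C = sum(ch == "C"),
              G = sum(ch == "G"), T = sum(ch == "T"),
              N = sum(!ch %in% c("A", "C", "G", "T")))
  A <- counts[["A"]]; T_ <- counts[["T"]]
  G <- counts[["G"]]; C <- counts[["C"]]
  acgt <- A + T_ + G + C
  structure(list(
    at_content = if (acgt > 0) (A + T_) / acgt else NA_real_,
    at_skew = if (A + T_ > 0) (A - T_) / (A + T_) else NA_real_,
    gc_skew = if (G + C > 0) (G - C) / (G + C) else NA_real_,
    counts = counts,
    n_excluded = counts[["N"]]
  ), class = "CompositionStats")
}

#' @export
print.CompositionStats <- function(x, ...) {
  cat(sprintf("AT content %.4f | AT skew %s | GC skew %s (%d excluded)\n",
              x$at_content,
              ifelse(is.na(x$at_skew), "NA", sprintf("%+.4f", x$at_skew)),
              ifelse(is.na(x$gc_skew), "NA", sprintf("%+.4f", x$gc_skew)),
              x$n_excluded))
  invisible(x)
}

#' Sliding-window composition deviation profile
#'
#' Per-window AT and GC content expressed as the deviation from the
#' whole-sequence means, the representation used for circular mitogenome
#' composition tracks. In circular mode windows start every `step` bp
#' from position 1 (`ceiling(L/step)` windows) and the final windows wrap
#' the origin; in linear mode there are `floor((L - window)/step) + 1`
#' windows.
#'
#' @param genome a [mito_genome()] or a nucleotide string.
#' @param window window width in bp (default 500).
#' @param step step in bp (default 100); `0 < step <= window <= length`.
#' @param circular wrap windows around the origin (default: the genome's
#'   topology, or `TRUE` for a bare string).
#' @return list of class `WindowProfile`: `window`, `step`, `positions`
#'   (window start coordinates), `at_deviation`, `gc_deviation`.
#' @export
window_profile <- function(genome, window = 500L, step = 100L,
                           circular = NULL) {
  if (inherits(genome, "MitoGenome")) {
    if (is.null(circular)) circular <- genome$topology == "circular"
    s <- genome$sequence
  } else {
    if (is.null(circular)) circular <- TRUE
    s <- toupper(genome)
  }
  L <- nchar(s)
  window <- as.integer(window); step <- as.integer(step)
  if (step <= 0L || window < step) stop("need 0 < step <= window")
  if (window > L) stop("window (", window, ") exceeds sequence length (",
                       L, ")")
  whole <- composition_stats(s)
  gc_content_of <- function(stats) {
    cc <- stats$counts
    acgt <- sum(cc[c("A", "C", "G", "T")])
    if (acgt > 0) (cc[["G"]] + cc[["C"]]) / acgt else NA_real_
  }
  mean_at <- whole$at_content
  mean_gc <- gc_content_of(whole)

  starts <- if (circular) seq.int(1L, L, by = step)
            else seq.int(1L, L - window + 1L, by = step)
  ext <- if (circular) paste0(s, substr(s, 1L, window)) else s
  at_dev <- gc_dev <- numeric(length(starts))
  ch <- seq_chars(ext)
  isA <- ch == "A"; isT <- ch == "T"; isG <- ch == "G"; isC <- ch == "C"
  cumA <- cumsum(isA); cumT <- cumsum(isT)
  cumG <- cumsum(isG); cumC <- cumsum(isC)
  win_count <- function(cum, from, to) cum[to] - if (from > 1L) cum[from - 1L] else 0L
  for (i in seq_along(starts)) {
    from <- starts[i]; to <- from + window - 1L
    A <- win_count(cumA, from, to); T_ <- win_count(cumT, from, to)
    G <- win_count(cumG, from, to); C <- win_count(cumC, from, to)
    acgt <- A + T_ + G + C
    at_dev[i] <- if (acgt > 0) (A + T_) / acgt - mean_at else NA_real_
    gc_dev[i] <- if (acgt > 0) (G + C) / acgt - mean_gc else NA_real_
  }
  structure(list(window = window, step = step, positions = starts,
                 at_deviation = at_dev, gc_deviation = gc_dev),
            class = "WindowProfile")
}

#' @export
print.WindowProfile <- function(x, ...) {
  cat("WindowProfile:", length(x$positions), "windows of", x$window,
      "bp, step", x$step, "bp\n")
  invisible(x)
}

#' Tabulate composition statistics for several genomes
#'
#' @param genomes a list of [mito_genome()] objects (or nucleotide
#'   strings; names are used as ids).
#' @return data.frame with one row per genome: `id`, `length`,
#'   `at_content`, `at_skew`, `gc_skew`, `n_excluded`.
#' @export
composition_table <- function(genomes) {
  rows <- lapply(seq_along(genomes), function(i) {
    g <- genomes[[i]]
    id <- if (inherits(g, "MitoGenome")) g$id else
      (names(genomes)[i] %||% paste0("seq", i))
    s <- if (inherits(g, "MitoGenome")) g$sequence else g
    cs <- composition_stats(s)
    data.frame(id = id, length = nchar(s), at_content = cs$at_content,
               at_skew = cs$at_skew, gc_skew = cs$gc_skew,
               n_excluded = cs$n_excluded, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
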