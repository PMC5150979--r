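#' Build the sliding-window skeleton over autosomes
#'
#' Tiles each autosome with overlapping windows of `window_size` bp starting
#' every `step` bp from position 0 (0-based, half-open). A window starts at
#' every multiple of `step` up to `length - step` (position 0 always starts
#' one), and the final windows are truncated at the chromosome end, so a
#' chromosome shorter than one window yields a single window covering it.
#' Chromosomes present in `chrom_lengths` but not listed in `autosomes`
#' (e.g. sex chromosomes, which experience different selective pressure and
#' effective population size) produce no windows.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param autosomes Character vector of chromosomes to window; defaults to
#'   all of `chrom_lengths`.
#' @param window_size Window width in bp (default 150 kb).
#' @param step Distance between window starts in bp (default 75 kb,
#'   half-window overlap). Must not exceed `window_size`: a larger step
#'   would leave gaps between windows.
#' @return A `window_frame`: list with `windows` (data.frame `chrom`,
#'   `start`, `end`, `window`), `window_size`, `step`, `chrom_lengths`,
#'   `autosomes`.
#' @examples
#' make_windows(c(chr1 = 300000), window_size = 150000, step = 75000)$windows
#' @export
make_windows <- function(chrom_lengths, autosomes = names(chrom_lengths),
                         window_size = 150000, step = 75000) {
  if (is.null(names(chrom_lengths))) stop("chrom_lengths must be named")
  if (step < 1) stop("step must be >= 1")
  if (step > window_size) {
    stop("step must not exceed window_size (gaps would break the overlapping tiling)")
  }
  absent <- setdiff(autosomes, names(chrom_lengths))
  if (length(absent)) {
    stop("autosomes missing from chrom_lengths: ", paste(absent, collapse = ", "))
  }
  pieces <- lapply(autosomes, function(chrom) {
    L <- chrom_lengths[[chrom]]
    k_max <- if (L <= step) 0 else (L - step) %/% step
    start <- step * (0:k_max)
    data.frame(chrom = chrom, start = start,
               end = pmin(start + window_size, L), stringsAsFactors = FALSE)
  })
  w <- do.call(rbind, pieces)
  w <- w[order(w$chrom, w$start), , drop = FALSE]
  w$window <- seq_len(nrow(w))
  rownames(w) <- NULL
  structure(list(windows = w, window_size = window_size, step = step,
                 chrom_lengths = chrom_lengths, autosomes = autosomes),
            class = "window_frame")
}

#' Assign SNPs to sliding windows
#'
#' A SNP at 1-based position `pos` (0-based `pos - 1`) belongs to every
#' window `[start, end)` containing it, i.e. up to
#' `ceiling(window_size / step)` windows. SNPs on chromosomes outside the
#' frame's autosomes are skipped and tallied in `n_skipped`.
#'
#' @param snps A [as_snp_table()] object.
#' @param frame A [make_windows()] frame.
#' @return The frame with `membership` (data.frame `window`, `snp` index
#'   pairs), `n_snps` (per-window SNP counts) and `n_skipped` filled in.
#' @export
assign_snps <- function(snps, frame) {
  stopifnot(inherits(frame, "window_frame"))
  w <- frame$windows
  step <- frame$step
  wsize <- frame$window_size
  mem <- vector("list", length(frame$autosomes))
  skipped <- 0L
  # per-chrom first window index and count, for local->global window ids
  first_idx <- tapply(w$window, w$chrom, min)
  n_win <- tapply(w$window, w$chrom, length)

  chroms <- snps$chrom
  x <- snps$pos - 1L  # 0-based
  for (i in seq_along(frame$autosomes)) {
    chrom <- frame$autosomes[i]
    idx <- which(chroms == chrom)
    if (!length(idx)) next
    xi <- x[idx]
    k_hi <- pmin(n_win[[chrom]] - 1L, xi %/% step)
    k_lo <- pmax(0L, (xi - wsize) %/% step + 1L)
    reps <- pmax(0L, k_hi - k_lo + 1L)
    snp_rep <- rep(idx, reps)
    k <- unlist(lapply(seq_along(xi), function(j)
      if (reps[j] > 0L) k_lo[j]:k_hi[j] else integer(0)))
    mem[[i]] <- data.frame(window = first_idx[[chrom]] + k, snp = snp_rep)
  }
  on_frame <- chroms %in% frame$autosomes
  skipped <- sum(!on_frame)

  membership <- do.call(rbind, mem)
  if (is.null(membership)) membership <- data.frame(window = integer(0), snp = integer(0))
  n_snps <- tabulate(membership$window, nbins = nrow(w))
  frame$membership <- membership
  frame$n_snps <- n_snps
  frame$n_skipped <- skipped
  frame
}

#' @export
print.window_frame <- function(x, ...) {
  cat(sprintf("window_frame: %d windows of %g bp (step %g bp) on %d autosome(s)\n",
              nrow(x$windows), x$window_size, x$step, length(x$autosomes)))
  if (!is.null(x$n_snps)) {
    cat(sprintf("SNPs assigned: %d membership records, %d SNP(s) off-frame\n",
                nrow(x$membership), x$n_skipped))
  }
  invisible(x)
}
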