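#' 4C-seq count container
#'
#' Holds a restriction-fragment map, raw per-end read counts, fragment scores
#' and sample metadata for one bait. The fragment score of a fragment is the
#' arithmetic mean of the read counts on its two mapping sites (the two
#' fragment ends), i.e. `score = (end1 + end2)/2` exactly.
#'
#' @param fragments data frame with columns `fragment_id`, `chrom`, `start`,
#'   `end` (0-based half-open); `mid` and `distance_to_bait` are derived if
#'   missing.
#' @param end1,end2 integer matrices (fragment x sample) of reads per mapping
#'   site. Either both or a precomputed `scores` matrix must be given.
#' @param samples data frame with at least `sample_id` and `condition`;
#'   typically also `time`, `genotype`, `replicate`.
#' @param bait list with `chrom` and `pos` (bp).
#' @param scores optional precomputed fragment-score matrix.
#' @return object of class `fourc_counts` with elements `fragments`,
#'   `scores`, `end1`, `end2`, `samples`, `bait`, logical vector `masked`
#'   (bait-adjacent exclusion; all `FALSE` until [mask_bait_adjacent()]), and
#'   `normalized` flag.
#' @export
new_fourc_counts <- function(fragments, end1 = NULL, end2 = NULL, samples,
                             bait, scores = NULL) {
  stopifnot(is.data.frame(fragments), is.data.frame(samples),
            all(c("fragment_id", "chrom", "start", "end") %in% names(fragments)),
            all(c("sample_id", "condition") %in% names(samples)),
            all(fragments$end > fragments$start))
  if (is.null(fragments$mid)) {
    fragments$mid <- (fragments$start + fragments$end) / 2
  }
  if (is.null(scores)) {
    stopifnot(!is.null(end1), !is.null(end2),
              all(dim(end1) == dim(end2)),
              nrow(end1) == nrow(fragments), ncol(end1) == nrow(samples))
    scores <- score_fragments(end1, end2)
  } else {
    stopifnot(nrow(scores) == nrow(fragments), ncol(scores) == nrow(samples))
  }
  bait_fragment <- which(fragments$chrom == bait$chrom &
                           fragments$start <= bait$pos &
                           fragments$end > bait$pos)
  if (length(bait_fragment) != 1L) bait_fragment <- NA_integer_
  if (is.null(fragments$distance_to_bait)) {
    fragments$distance_to_bait <- ifelse(fragments$chrom == bait$chrom,
                                         fragments$mid - bait$pos, NA_real_)
  }
  structure(list(fragments = fragments, scores = scores,
                 end1 = end1, end2 = end2, samples = samples,
                 bait = c(bait, list(fragment = bait_fragment)),
                 masked = rep(FALSE, nrow(fragments)),
                 normalized = FALSE),
            class = "fourc_counts")
}

#' @export
print.fourc_counts <- function(x, ...) {
  cat(sprintf("<fourc_counts> %d fragments x %d samples, bait %s:%d%s%s\n",
              nrow(x$fragments), nrow(x$samples), x$bait$chrom,
              as.integer(x$bait$pos),
              if (any(x$masked)) sprintf(", %d masked", sum(x$masked)) else "",
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' In-silico restriction digest of a genome
#'
#' Cuts each sequence at every occurrence of the (non-degenerate) recognition
#' motif, placing fragment boundaries at the motif start, so fragments tile
#' each chromosome exactly: the first fragment begins at 0 and the last ends
#' at the sequence length. Coordinates are 0-based half-open. A sequence with
#' no motif occurrence yields one whole-chromosome fragment with a warning.
#'
#' @param sequence a `Biostrings::DNAStringSet`, a named character vector of
#'   sequences, or a path to a FASTA file.
#' @param site recognition motif (default `"GATC"`, DpnII).
#' @return data frame (fragment map) with columns `fragment_id`, `chrom`,
#'   `start`, `end`, `mid`.
#' @examples
#' digest_genome(c(chr1 = "AAGATCAA"))  # fragments [0,2) and [2,8)
#' @export
digest_genome <- function(sequence, site = "GATC") {
  stopifnot(nchar(site) >= 1)
  if (grepl("[^ACGTacgt]", site)) stop("degenerate motifs are not supported")
  if (is.character(sequence) && length(sequence) == 1L && file.exists(sequence)) {
    sequence <- Biostrings::readDNAStringSet(sequence)
  }
  if (is.character(sequence)) {
    sequence <- Biostrings::DNAStringSet(sequence)
  }
  stopifnot(methods::is(sequence, "DNAStringSet"), length(sequence) >= 1)
  if (is.null(names(sequence))) {
    names(sequence) <- paste0("seq", seq_along(sequence))
  }
  maps <- lapply(seq_along(sequence), function(k) {
    len <- Biostrings::width(sequence)[k]
    hits <- Biostrings::start(Biostrings::matchPattern(site, sequence[[k]]))
    cuts <- hits - 1L  # 0-based cut positions at motif start
    cuts <- cuts[cuts > 0 & cuts < len]
    if (length(cuts) == 0L) {
      warning(sprintf("no '%s' site in %s: single whole-chromosome fragment",
                      site, names(sequence)[k]))
    }
    starts <- c(0L, cuts)
    ends <- c(cuts, len)
    data.frame(chrom = names(sequence)[k], start = starts, end = ends)
  })
  map <- do.call(rbind, maps)
  map$fragment_id <- seq_len(nrow(map))
  map$mid <- (map$start + map$end) / 2
  map[, c("fragment_id", "chrom", "start", "end", "mid")]
}

#' Fragment score from the two mapping-site counts
#'
#' Each restriction fragment carries two mapping sites (its two ends); the
#' fragment score is the average of the reads per mapping site.
#'
#' @param end1,end2 non-negative numeric vectors or matrices of identical
#'   shape.
#' @return `(end1 + end2) / 2`, same shape.
#' @export
score_fragments <- function(end1, end2) {
  if (any(end1 < 0, na.rm = TRUE) || any(end2 < 0, na.rm = TRUE)) {
    stop("negative counts")
  }
  stopifnot(length(end1) == length(end2))
  # a missing end is treated as zero reads (dropout); the downstream w_s
  # condition weights absorb the resulting zeros
  end1[is.na(end1)] <- 0
  end2[is.na(end2)] <- 0
  (end1 + end2) / 2
}

#' Per-sample 4C quality control
#'
#' A sample fails QC when at least 75% of the restriction fragments inside a
#' window of +/- `window` bp around the bait carry no counts at all (the
#' boundary is included: exactly 75% zero fails).
#'
#' @param counts a `fourc_counts`.
#' @param window half-width of the bait window in bp (default 1 Mb).
#' @return data frame (QC report) with `sample_id`, `zero_fraction`, `pass`.
#' @export
qc_sample <- function(counts, window = 1e6) {
  stopifnot(inherits(counts, "fourc_counts"))
  fr <- counts$fragments
  in_win <- fr$chrom == counts$bait$chrom &
    abs(fr$mid - counts$bait$pos) <= window
  if (!any(in_win)) stop("no fragments in the bait window")
  zf <- colMeans(counts$scores[in_win, , drop = FALSE] == 0)
  data.frame(sample_id = counts$samples$sample_id,
             zero_fraction = unname(zf),
             pass = unname(zf) < 0.75)
}

#' Mask the bait fragment and its immediate neighbours
#'
#' The first `k` fragments upstream of and downstream from the bait (2k in
#' total), plus the bait fragment itself, are flagged as excluded: they are
#' dominated by self-ligation and partial-digestion products. If a side has
#' fewer than `k` fragments, what exists is masked with a warning.
#'
#' @param counts a `fourc_counts` whose bait falls inside a fragment.
#' @param k fragments to mask on each side (default 5).
#' @return the `fourc_counts` with its `masked` vector updated.
#' @export
mask_bait_adjacent <- function(counts, k = 5) {
  stopifnot(inherits(counts, "fourc_counts"), k >= 0)
  bf <- counts$bait$fragment
  if (is.na(bf)) stop("bait fragment not identified")
  fr <- counts$fragments
  on_cis <- which(fr$chrom == counts$bait$chrom)
  pos_in_cis <- match(bf, on_cis)
  lo <- pos_in_cis - k; hi <- pos_in_cis + k
  if (lo < 1 || hi > length(on_cis)) {
    warning("fewer than k fragments on one side of the bait; masking what exists")
    lo <- max(1, lo); hi <- min(length(on_cis), hi)
  }
  counts$masked[on_cis[lo:hi]] <- TRUE
  counts
}

#' Library-size normalization on the cis chromosome
#'
#' Rescales each sample's fragment scores so that every sample has the same
#' total score on the cis chromosome, excluding the masked bait-adjacent
#' fragments. The common target is the mean of the per-sample cis sums, so
#' the factors are invariant to a global rescaling of all samples.
#'
#' @param counts a `fourc_counts`, after [mask_bait_adjacent()].
#' @return the `fourc_counts` with rescaled `scores`, `normalized = TRUE` and
#'   the per-sample factors in `norm_factors`.
#' @export
normalize_library <- function(counts) {
  stopifnot(inherits(counts, "fourc_counts"))
  if (!any(counts$masked)) {
    warning("normalizing without bait masking; call mask_bait_adjacent() first")
  }
  cis <- counts$fragments$chrom == counts$bait$chrom & !counts$masked
  cis_sum <- colSums(counts$scores[cis, , drop = FALSE])
  if (any(cis_sum <= 0)) stop("sample with zero cis sum")
  factors <- mean(cis_sum) / cis_sum
  counts$scores <- sweep(counts$scores, 2, factors, `*`)
  counts$norm_factors <- factors
  counts$normalized <- TRUE
  counts
}

#' Fraction of cis contacts within the bait-proximal window
#'
#' Per sample: the summed score of unmasked fragments within +/- `window` bp
#' of the bait, divided by the summed score of all unmasked cis fragments.
#'
#' @param counts a normalized `fourc_counts`.
#' @param window half-width (bp); the default 1 Mb on each side spans the
#'   first 2 Mb surrounding the bait.
#' @return named numeric vector, one fraction per sample.
#' @export
cis_fraction <- function(counts, window = 1e6) {
  stopifnot(inherits(counts, "fourc_counts"))
  fr <- counts$fragments
  cis <- fr$chrom == counts$bait$chrom & !counts$masked
  in_win <- cis & abs(fr$mid - counts$bait$pos) <= window
  tot <- colSums(counts$scores[cis, , drop = FALSE])
  if (any(tot <= 0)) stop("sample with zero cis sum")
  win <- colSums(counts$scores[in_win, , drop = FALSE])
  stats::setNames(win / tot, counts$samples$sample_id)
}

#' Write a fragment map as BED6
#'
#' @param fragments fragment-map data frame.
#' @param path output path.
#' @export
write_fragment_bed <- function(fragments, path) {
  bed <- data.frame(fragments$chrom, fragments$start, fragments$end,
                    fragments$fragment_id, 0, "+")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read a 4C count matrix as TSV
#'
#' Long format: one row per fragment x sample with both end counts and the
#' score, plus a companion sample-metadata TSV.
#'
#' @param counts a `fourc_counts`.
#' @param path counts TSV path; metadata goes to `<path>.samples.tsv`.
#' @export
write_fourc_tsv <- function(counts, path) {
  stopifnot(inherits(counts, "fourc_counts"))
  fr <- counts$fragments
  ns <- nrow(counts$samples)
  long <- data.frame(
    fragment_id = rep(fr$fragment_id, times = ns),
    chrom = rep(fr$chrom, times = ns),
    start = rep(fr$start, times = ns),
    end = rep(fr$end, times = ns),
    end1_count = if (!is.null(counts$end1)) as.vector(counts$end1) else NA,
    end2_count = if (!is.null(counts$end2)) as.vector(counts$end2) else NA,
    score = as.vector(counts$scores),
    sample_id = rep(counts$samples$sample_id, each = nrow(fr))
  )
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(counts$samples, paste0(path, ".samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export one per-fragment value vector as bedGraph
#' @param fragments fragment map rows matching `value`.
#' @param value numeric vector.
#' @param path output path.
#' @param name track name line.
#' @export
write_bedgraph <- function(fragments, value, path, name = "rhythm4c") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s\"", name), con)
  utils::write.table(data.frame(fragments$chrom, fragments$start,
                                fragments$end, value),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
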