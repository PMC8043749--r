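# Readers and writers for the package's plain-text dialects.
# Frame indices are 0-based in every file.

#' Read and write prediction stream CSVs
#'
#' Long format `frame,prob` (one file per stream) or wide format
#' `frame,prob_1,...,prob_k`.
#'
#' @param path file path.
#' @param fps frames per second to attach (default 30).
#' @return A list of [prediction_series] (length 1 for long format).
#' @export
read_predictions_csv <- function(path, fps = 30) {
  d <- utils::read.csv(path)
  .assert(names(d)[1] == "frame", "first column must be 'frame'")
  d <- d[order(d$frame), , drop = FALSE]
  lapply(d[-1], prediction_series, fps = fps)
}

#' @rdname read_predictions_csv
#' @param streams list of [prediction_series] of equal length.
#' @export
write_predictions_csv <- function(streams, path) {
  P <- do.call(cbind, lapply(streams, `[[`, "probs"))
  colnames(P) <- sprintf("prob_%d", seq_along(streams))
  utils::write.csv(data.frame(frame = seq_len(nrow(P)) - 1L, P), path,
                   row.names = FALSE, quote = FALSE)
}

#' Read and write ethogram CSVs (`frame,label`, label 0/1)
#'
#' @param path file path.
#' @param fps frames per second.
#' @return An [ethogram].
#' @export
read_ethogram_csv <- function(path, fps = 30) {
  d <- utils::read.csv(path)
  d <- d[order(d$frame), , drop = FALSE]
  ethogram(d$label, fps = fps)
}

#' @rdname read_ethogram_csv
#' @param eth an [ethogram].
#' @export
write_ethogram_csv <- function(eth, path) {
  utils::write.csv(data.frame(frame = seq_along(eth$labels) - 1L,
                              label = eth$labels),
                   path, row.names = FALSE, quote = FALSE)
}

#' Read and write track CSVs (`frame,x,y,w,l`)
#'
#' @param path file path.
#' @param fps frames per second.
#' @return An [ellipse_track].
#' @export
read_track_csv <- function(path, fps = 30) {
  d <- utils::read.csv(path)
  d <- d[order(d$frame), , drop = FALSE]
  ellipse_track(d$x, d$y, d$w, d$l, fps = fps)
}

#' @rdname read_track_csv
#' @param track an [ellipse_track].
#' @export
write_track_csv <- function(track, path) {
  utils::write.csv(data.frame(frame = seq_along(track$x) - 1L,
                              x = track$x, y = track$y,
                              w = track$W, l = track$L),
                   path, row.names = FALSE, quote = FALSE)
}

#' Write a bout table as TSV (seconds scale)
#'
#' @param bouts a `bout_table` from [segment_bouts()].
#' @param path output path.
#' @param fps frames per second used for the frame indices.
#' @export
write_bouts_tsv <- function(bouts, path, fps = attr(bouts, "fps")) {
  if (is.null(fps)) fps <- 30
  utils::write.table(
    data.frame(start_s = bouts$start / fps, end_s = bouts$end / fps,
               groomed_s = bouts$groomed_s, span_s = bouts$span_s,
               n_pauses = bouts$n_pauses),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Read gene intervals from BED or GFF3
#'
#' BED input is converted from 0-based half-open to the package's 1-based
#' inclusive convention; GFF3 is already 1-based. Gene names come from the
#' BED name column or the GFF3 `Name`/`ID` attribute.
#'
#' @param path a `.bed`, `.gff`/`.gff3` file.
#' @return Data frame `gene`, `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_gene_intervals <- function(path) {
  gr <- rtracklayer::import(path)
  nm <- if (!is.null(gr$name)) gr$name
        else if (!is.null(gr$Name)) gr$Name
        else if (!is.null(gr$ID)) gr$ID
        else sprintf("feature%d", seq_along(gr))
  data.frame(gene = as.character(nm),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Export QTL spans as BED
#'
#' Emits one record per locus (0-based half-open coordinates), named by the
#' peak SNP with score `-log10(peak p)`.
#'
#' @param qtls a `qtl_table` from [greedy_qtl()].
#' @param path output `.bed` path.
#' @export
write_qtl_bed <- function(qtls, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(qtls$chrom),
    ranges = IRanges::IRanges(start = qtls$start_bp, end = qtls$end_bp),
    name = qtls$peak_snp,
    score = pmin(-log10(qtls$peak_p), 1000))
  rtracklayer::export(gr, path, format = "BED")
}

#' Write an association scan as TSV (`snp,chrom,bp,beta,se,p`)
#'
#' @param assoc an `assoc_result`.
#' @param path output path.
#' @export
write_assoc_tsv <- function(assoc, path) {
  utils::write.table(as.data.frame(assoc)[, c("snp", "chrom", "bp",
                                              "beta", "se", "p")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
}
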