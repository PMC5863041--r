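#' Read paired-end fragments from BED or BAM
#'
#' Fragments are genomic intervals covered by one sequenced DNA template.
#' BED input is taken as-is (0-based half-open). For coordinate-sorted BAM
#' with proper pairs, one fragment per template is reconstructed from the
#' leftmost mate position and the template length (TLEN); records that are
#' not part of a proper pair are skipped with a warning count.
#'
#' @param path file path.
#' @param format `"bed"` or `"bam"` (default guessed from the extension).
#' @param max_length fragments with length > `max_length` are dropped
#'   (default 2000, mirroring the aligner's maximal template size) with a
#'   message reporting the count.
#' @return fragment tibble (chrom, start, end, name, score, strand).
#' @export
read_fragments <- function(path, format = NULL, max_length = 2000L) {
  stop_if_not(file.exists(path), sprintf("file not found: %s", path))
  if (is.null(format)) {
    format <- if (grepl("\\.bam$", path, ignore.case = TRUE)) "bam" else "bed"
  }
  format <- match.arg(format, c("bed", "bam"))
  fs <- if (format == "bed") read_bed(path) else read_bam_fragments(path)
  too_long <- fs$end - fs$start > max_length
  if (any(too_long)) {
    message(sprintf("dropped %d fragment(s) longer than %d bp",
                    sum(too_long), max_length))
    fs <- fs[!too_long, ]
  }
  fs
}

# BED3-BED6 reader; extra columns beyond 6 ignored. Malformed lines abort
# with the offending line number.
read_bed <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0 || all(lines == "")) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), score = numeric(), strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3)
  if (length(bad) > 0) {
    abort(sprintf("malformed BED line %d: fewer than 3 fields", bad[1]))
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3)))
  bad <- which(is.na(start) | is.na(end) | end <= start)
  if (length(bad) > 0) {
    abort(sprintf("malformed BED line %d: invalid interval", bad[1]))
  }
  get_col <- function(k, default) {
    vapply(fields, function(f) if (length(f) >= k) f[k] else default, "")
  }
  tibble(chrom = vapply(fields, `[`, "", 1),
         start = start, end = end,
         name = get_col(4, "."),
         score = suppressWarnings(as.numeric(get_col(5, "0"))),
         strand = get_col(6, "."))
}

read_bam_fragments <- function(path) {
  param <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "isize", "flag"))
  b <- Rsamtools::scanBam(path, param = param)[[1]]
  flag <- b$flag
  proper <- bitwAnd(flag, 2L) > 0L
  n_skipped <- sum(!proper)
  if (n_skipped > 0) {
    warn(sprintf("skipped %d record(s) not in a proper pair", n_skipped))
  }
  keep <- proper & !is.na(b$isize) & b$isize > 0L  # leftmost mate once/template
  start <- b$pos[keep] - 1L
  tibble(chrom = as.character(b$rname[keep]),
         start = start, end = start + b$isize[keep],
         name = ".", score = 0, strand = ".")
}

#' Write fragments as BED6
#' @param fs fragment tibble.
#' @param path output path.
#' @export
write_bed <- function(fs, path) {
  fs <- check_fragments(fs)
  out <- tibble(chrom = fs$chrom, start = fs$start, end = fs$end,
                name = if ("name" %in% names(fs)) fs$name else ".",
                score = if ("score" %in% names(fs)) fs$score else 0L,
                strand = if ("strand" %in% names(fs)) fs$strand else ".")
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Filter fragments by length (half-open on the right)
#'
#' Retains fragments with `min_length <= length` and, when `max_length`
#' is given, `length < max_length` — so "shorter than 80 bp" is exactly
#' `select_by_length(fs, 1, 80)`.
#'
#' @param fs fragment tibble.
#' @param min_length integer >= 1.
#' @param max_length exclusive upper bound, or `NULL` for none.
#' @return filtered fragment tibble.
#' @export
select_by_length <- function(fs, min_length = 1L, max_length = NULL) {
  fs <- check_fragments(fs)
  stop_if_not(min_length >= 1, "`min_length` must be >= 1")
  if (!is.null(max_length)) {
    stop_if_not(min_length < max_length,
                "`min_length` must be smaller than `max_length`")
  }
  len <- fs$end - fs$start
  keep <- len >= min_length
  if (!is.null(max_length)) keep <- keep & len < max_length
  fs[keep, ]
}

#' Scan a FASTA file for IUPAC consensus matches on both strands
#'
#' Exact matching under IUPAC ambiguity codes; minus-strand occurrences
#' are matches of the reverse complement, reported in forward coordinates.
#'
#' @param fasta_path FASTA file.
#' @param pattern IUPAC consensus string (e.g. `"TTACCCG"`).
#' @return tibble chrom, start, end (0-based half-open), strand,
#'   pattern_id.
#' @export
scan_consensus <- function(fasta_path, pattern) {
  stop_if_not(file.exists(fasta_path),
              sprintf("file not found: %s", fasta_path))
  pattern <- toupper(pattern)
  ok <- strsplit(pattern, "")[[1]] %in%
    names(Biostrings::IUPAC_CODE_MAP)
  if (!all(ok)) {
    abort(sprintf("invalid IUPAC symbol in pattern: %s",
                  paste(unique(strsplit(pattern, "")[[1]][!ok]),
                        collapse = ", ")))
  }
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  fwd <- Biostrings::DNAString(pattern)
  rev <- Biostrings::reverseComplement(fwd)
  one_strand <- function(pat, strand) {
    hits <- Biostrings::vmatchPattern(pat, seqs, fixed = FALSE)
    purrr::map2(as.list(hits), names(seqs), function(ir, ch) {
      tibble(chrom = ch, start = IRanges::start(ir) - 1L,
             end = IRanges::end(ir), strand = strand,
             pattern_id = pattern)
    }) |> dplyr::bind_rows()
  }
  out <- dplyr::bind_rows(one_strand(fwd, "+"), one_strand(rev, "-"))
  dplyr::arrange(out, .data$chrom, .data$start, .data$strand)
}

#' Per-base fragment coverage as a bedGraph-style tibble
#'
#' Coverage is the number of fragments overlapping each base; total mass
#' (sum of `value * (end - start)`) equals the summed fragment lengths.
#'
#' @param fs fragment tibble.
#' @param keep_zero keep zero-coverage runs between fragments
#'   (default FALSE, the usual sparse bedGraph).
#' @return tibble chrom, start, end, value with constant-coverage runs.
#' @export
coverage_track <- function(fs, keep_zero = FALSE) {
  fs <- check_fragments(fs)
  if (nrow(fs) == 0) {
    return(tibble(chrom = character(), start = integer(),
                  end = integer(), value = numeric()))
  }
  cov <- coverage_rle(fs)
  out <- purrr::imap(cov, function(rle, ch) {
    v <- S4Vectors::runValue(rle)
    l <- S4Vectors::runLength(rle)
    end <- cumsum(as.numeric(l))
    tibble(chrom = ch, start = as.integer(end - l), end = as.integer(end),
           value = as.numeric(v))
  }) |> dplyr::bind_rows()
  if (!keep_zero) out <- out[out$value > 0, ]
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Write a coverage track as bedGraph
#' @param track tibble from [coverage_track()].
#' @param path output path.
#' @param track_line optional UCSC track line to prepend.
#' @export
write_bedgraph <- function(track, path, track_line = NULL) {
  if (!is.null(track_line)) {
    readr::write_lines(track_line, path)
    readr::write_tsv(track, path, col_names = FALSE, append = TRUE)
  } else {
    readr::write_tsv(track, path, col_names = FALSE)
  }
  invisible(path)
}

#' Read a bedGraph file
#' @param path bedGraph path (track lines ignored).
#' @return tibble chrom, start, end, value.
#' @export
read_bedgraph <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & lines != ""]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(),
                  end = integer(), value = numeric()))
  }
  d <- readr::read_tsv(I(lines), col_names = c("chrom", "start", "end", "value"),
                       col_types = "ciid", progress = FALSE)
  as_tibble(d)
}

#' Read stranded 1-bp 3'-end reads from BED6
#'
#' @param path BED6 path; each interval must be 1 bp wide and stranded.
#' @return tibble chrom, pos, strand (pos = the 3'-end base, 0-based).
#' @export
read_stranded_reads <- function(path) {
  b <- read_bed(path)
  stop_if_not(all(b$end - b$start == 1L),
              "stranded 3'-end reads must be 1-bp intervals")
  stop_if_not(all(b$strand %in% c("+", "-")),
              "stranded reads must have strand '+' or '-'")
  tibble(chrom = b$chrom, pos = b$start, strand = b$strand, name = b$name)
}

#' Write stranded 3'-end reads as BED6 with 1-bp intervals
#' @param reads tibble with chrom, pos, strand (and optional name).
#' @param path output path.
#' @export
write_stranded_reads <- function(reads, path) {
  out <- tibble(chrom = reads$chrom, start = reads$pos,
                end = reads$pos + 1L,
                name = if ("site_id" %in% names(reads)) {
                  paste0(reads$site_id, ":", reads$read_class)
                } else if ("name" %in% names(reads)) reads$name else ".",
                score = 0L, strand = reads$strand)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a genome annotation from TSV tables
#'
#' @param tss_path TSV with columns chrom, pos, strand, gene_id (TSS per
#'   gene, 0-based position).
#' @param orf_path optional TSV with chrom, start, end (half-open ORF
#'   intervals) and optional gene_id.
#' @param telomere_path optional TSV with chrom, start, end.
#' @return list with tibbles `tss`, `orf`, `telomeres`.
#' @export
read_annotation <- function(tss_path, orf_path = NULL, telomere_path = NULL) {
  tss <- readr::read_tsv(tss_path, col_types = readr::cols(), progress = FALSE)
  stop_if_not(all(c("chrom", "pos", "strand") %in% names(tss)),
              "TSS table needs chrom, pos, strand")
  read_iv <- function(p) {
    if (is.null(p)) return(tibble(chrom = character(), start = integer(),
                                  end = integer()))
    d <- readr::read_tsv(p, col_types = readr::cols(), progress = FALSE)
    stop_if_not(all(c("chrom", "start", "end") %in% names(d)),
                "interval table needs chrom, start, end")
    stop_if_not(all(d$end > d$start), "intervals must satisfy end > start")
    as_tibble(d)
  }
  list(tss = as_tibble(tss), orf = read_iv(orf_path),
       telomeres = read_iv(telomere_path))
}

#' Genome annotation implied by a simulated site panel
#'
#' One gene per site: the TSS sits `tss_offset` from the motif center on
#' the gene strand, with a 1-kb ORF starting 50 bp downstream of the TSS.
#'
#' @param panel a site panel.
#' @return annotation list (`tss`, `orf`, `telomeres`) as in
#'   [read_annotation()].
#' @export
panel_annotation <- function(panel) {
  s <- panel$sites
  tss_pos <- s$motif_center + s$tss_offset
  dir <- sign(s$tss_offset)
  orf_start <- ifelse(dir > 0, tss_pos + 50L, tss_pos - 50L - 1000L)
  list(
    tss = tibble(chrom = s$chrom, pos = as.integer(tss_pos),
                 strand = s$tss_strand, gene_id = paste0("gene_", s$site_id)),
    orf = tibble(chrom = s$chrom, start = as.integer(orf_start),
                 end = as.integer(orf_start + 1000L),
                 gene_id = paste0("gene_", s$site_id)),
    telomeres = panel$telomeres)
}
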