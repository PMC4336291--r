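#' Describe an amplicon with a degenerate-codon variable region
#'
#' An amplicon spec records the two fixed flanking sequences of a
#' saturation-mutagenesis amplicon and the degenerate-codon pattern of the
#' variable region between them. The defaults describe a three-codon SNS
#' library (S = G/C, N = any base) in the central transmembrane region of the
#' *E. coli* toxin HokC: SNS codons encode 10 amino acids
#' (L, P, H, Q, R, V, A, D, E, G) and no stop codon.
#'
#' The wild-type template sequence of a mutagenised region generally does not
#' itself match the degeneracy pattern (no SNS codon encodes Ile or Thr, the
#' first two wild-type residues here). Since the wild-type variant is a
#' legitimate member of the screen — and a particularly informative one for
#' ISPA detection — `wildtype_dna` whitelists one region sequence that is
#' accepted even though it fails the pattern. Set it to `NULL` to disable.
#'
#' @param flank5,flank3 Fixed flanking DNA (uppercase A/C/G/T) immediately
#'   5' and 3' of the variable region.
#' @param n_variable_codons Number of degenerate codons between the flanks.
#' @param degeneracy_pattern Three-letter IUPAC-style codon pattern applied to
#'   every variable codon, e.g. `"SNS"`, `"NNK"`, `"NNS"`.
#' @param wildtype_dna Optional region sequence accepted despite failing the
#'   pattern (the template's own codons). Default is a synthetic stand-in
#'   translating to Ile-Thr-Ala, the HokC wild-type residues 16-18.
#' @param max_flank_mismatch Number of mismatches tolerated when locating each
#'   flank. Default 0: flanks must match exactly.
#'
#' @return An object of class `"amplicon_spec"`.
#' @examples
#' amplicon_spec()
#' amplicon_spec(degeneracy_pattern = "NNK", wildtype_dna = NULL)
#' @export
amplicon_spec <- function(flank5 = "CCTGATCGTCATCTGT",
                          flank3 = "GTAGTGGCGG",
                          n_variable_codons = 3L,
                          degeneracy_pattern = "SNS",
                          wildtype_dna = "ATTACCGCA",
                          max_flank_mismatch = 0L) {
  stopifnot(is.character(flank5), length(flank5) == 1L, nzchar(flank5),
            is.character(flank3), length(flank3) == 1L, nzchar(flank3))
  if (grepl("[^ACGT]", flank5) || grepl("[^ACGT]", flank3)) {
    stop("flanks must be uppercase A/C/G/T only", call. = FALSE)
  }
  n_variable_codons <- as.integer(n_variable_codons)
  if (is.na(n_variable_codons) || n_variable_codons < 1L) {
    stop("`n_variable_codons` must be a positive integer", call. = FALSE)
  }
  if (nchar(degeneracy_pattern) != 3L ||
      grepl("[^ACGTRYSWKMBDHVN]", degeneracy_pattern)) {
    stop("`degeneracy_pattern` must be 3 IUPAC letters", call. = FALSE)
  }
  region_len <- 3L * n_variable_codons
  if (!is.null(wildtype_dna)) {
    stopifnot(is.character(wildtype_dna), length(wildtype_dna) == 1L)
    if (nchar(wildtype_dna) != region_len || grepl("[^ACGT]", wildtype_dna)) {
      stop("`wildtype_dna` must be ", region_len, " nt of A/C/G/T",
           call. = FALSE)
    }
  }
  structure(
    list(flank5 = flank5, flank3 = flank3,
         n_variable_codons = n_variable_codons,
         degeneracy_pattern = degeneracy_pattern,
         wildtype_dna = wildtype_dna,
         max_flank_mismatch = as.integer(max_flank_mismatch),
         region_length = region_len),
    class = "amplicon_spec"
  )
}

#' @export
print.amplicon_spec <- function(x, ...) {
  cat("<amplicon_spec> ", x$flank5, " [",
      paste(rep(x$degeneracy_pattern, x$n_variable_codons), collapse = " "),
      "] ", x$flank3, "\n", sep = "")
  if (!is.null(x$wildtype_dna)) {
    cat("  wild-type region whitelisted:", x$wildtype_dna, "\n")
  }
  invisible(x)
}

# IUPAC code -> allowed bases, for pattern checks
.iupac <- c(A = "A", C = "C", G = "G", T = "T",
            R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
            B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

#' Enumerate the amino acids encoded by a degenerate codon pattern
#'
#' Expands a three-letter IUPAC codon pattern into its codons and translates
#' them with the standard genetic code. For `"SNS"` this yields exactly the
#' 10-letter alphabet L, P, H, Q, R, V, A, D, E, G and no stop codon.
#'
#' @param pattern Three-letter IUPAC codon pattern.
#' @return A tibble with columns `codon` and `aa`, one row per codon.
#' @examples
#' sns <- degenerate_codon_table("SNS")
#' sort(unique(sns$aa))
#' @export
degenerate_codon_table <- function(pattern = "SNS") {
  stopifnot(nchar(pattern) == 3L)
  sets <- strsplit(.iupac[strsplit(pattern, "")[[1]]], "")
  if (anyNA(names(sets)) || any(lengths(sets) == 0L)) {
    stop("invalid IUPAC letter in pattern", call. = FALSE)
  }
  grid <- expand.grid(p1 = sets[[1]], p2 = sets[[2]], p3 = sets[[3]],
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  codon <- paste0(grid$p1, grid$p2, grid$p3)
  tibble::tibble(codon = codon,
                 aa = unname(Biostrings::GENETIC_CODE[codon]))
}

#' Translate a variable-region DNA sequence
#'
#' Standard-genetic-code translation (vectorised). Uses the
#' [Biostrings::GENETIC_CODE] table codon-by-codon, so no initiator-codon
#' special-casing is applied — a lone CTG translates to L, never M.
#'
#' @param dna Character vector of A/C/G/T sequences, each with length a
#'   multiple of 3. Empty strings translate to empty strings.
#' @return Character vector of peptides ("*" for a stop codon).
#' @examples
#' translate_region("CACCTGGAG") # "HLE"
#' @export
translate_region <- function(dna) {
  if (length(dna) == 0L) return(character(0))
  stopifnot(is.character(dna))
  if (any(nchar(dna) %% 3L != 0L)) {
    stop("sequence length must be a multiple of 3", call. = FALSE)
  }
  if (any(grepl("[^ACGT]", dna))) {
    stop("non-ACGT base in sequence", call. = FALSE)
  }
  vapply(dna, function(s) {
    if (!nzchar(s)) return("")
    cods <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    paste(Biostrings::GENETIC_CODE[cods], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Read one phenotype pool of amplicon reads
#'
#' Reads a FASTA or FASTQ file (gzip transparently accepted, format
#' auto-detected from the first record marker) and tags every read with its
#' phenotype pool. Qualities, if present, are not used downstream; reads are
#' uppercased.
#'
#' @param path Path to a FASTA/FASTQ(.gz) file.
#' @param phenotype `"WT"` or `"MUT"`: which phenotype pool the file holds
#'   (pools arrive as separate files).
#' @param format `"auto"` (default), `"fasta"` or `"fastq"`.
#' @return A tibble with columns `read_id`, `seq`, `phenotype`.
#' @export
read_pool <- function(path, phenotype = c("WT", "MUT"),
                      format = c("auto", "fasta", "fastq")) {
  phenotype <- match.arg(phenotype)
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    con <- gzfile(path, "rt")
    on.exit(close(con), add = TRUE)
    first <- readLines(con, n = 1L)
    format <- if (length(first) == 0L || !startsWith(first, "@")) "fasta"
              else "fastq"
  }
  if (format == "fastq") .validate_fastq(path)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = format),
    error = function(e) {
      stop("malformed ", toupper(format), " in ", path, ": ",
           conditionMessage(e), call. = FALSE)
    }
  )
  ids <- names(seqs)
  if (is.null(ids)) ids <- as.character(seq_along(seqs))
  tibble::tibble(
    read_id = unname(ids),
    seq = unname(toupper(as.character(seqs))),
    phenotype = rep(phenotype, length(seqs))
  )
}

# 4-line-record structure check; Biostrings silently tolerates a truncated
# final record, which would let a corrupt file pass unnoticed
.validate_fastq <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con), add = TRUE)
  n <- 0L
  repeat {
    chunk <- readLines(con, n = 40000L)
    if (length(chunk) == 0L) break
    n <- n + length(chunk)
  }
  if (n %% 4L != 0L) {
    stop("malformed FASTQ in ", path, ": truncated record ",
         n %/% 4L + 1L, call. = FALSE)
  }
  invisible(TRUE)
}

# locate `pattern` in `seq` allowing up to mm mismatches; leftmost start or NA
.find_flank <- function(seqs, pattern, mm) {
  if (mm == 0L) {
    pos <- stringr::str_locate(seqs, stringr::fixed(pattern))[, "start"]
    nhit <- stringr::str_count(seqs, stringr::fixed(pattern))
  } else {
    hits <- Biostrings::vmatchPattern(pattern,
                                      Biostrings::DNAStringSet(seqs),
                                      max.mismatch = mm)
    starts <- Biostrings::startIndex(hits)
    pos <- vapply(starts, function(s) if (length(s)) min(s) else NA_integer_,
                  integer(1))
    nhit <- lengths(starts)
  }
  list(pos = pos, nhit = nhit)
}

#' Extract and validate variable regions from tagged reads
#'
#' For every read, locates the 5' flank (exact by default; the read is also
#' searched in reverse complement if the flanks are not found in the given
#' orientation, since Illumina pools are unstranded), then the 3' flank, and
#' accepts the sequence in between only if it has the expected length and
#' every codon matches the degeneracy pattern (or equals the whitelisted
#' wild-type region). The per-codon pattern check doubles as the
#' genomic-contamination filter: spiked-in genomic DNA lacks the SNS codon
#' composition and/or the flanks and is rejected.
#'
#' Rejection reasons:
#' \describe{
#'   \item{NO_FLANK}{one or both flanks not found (in either orientation)}
#'   \item{WRONG_LENGTH}{flanks found but the gap is not `3 * n_variable_codons`}
#'   \item{NON_SNS}{region has the right length but a codon violates the pattern}
#' }
#'
#' If a flank matches more than once the leftmost match is used and a warning
#' is issued. Every input read appears in the output exactly once
#' (accepted + rejected = input).
#'
#' @param reads A tibble with columns `seq` and `phenotype` (from
#'   [read_pool()]), or a character vector of sequences.
#' @param spec An [amplicon_spec()].
#' @return The input tibble plus columns `status` (`"ACCEPTED"` or a rejection
#'   tag), `variant_dna` (NA unless accepted) and `variant_aa`.
#' @examples
#' sp <- amplicon_spec()
#' extract_variable_region(paste0("AA", sp$flank5, "CACCTGGAG", sp$flank3), sp)
#' @export
extract_variable_region <- function(reads, spec = amplicon_spec()) {
  stopifnot(inherits(spec, "amplicon_spec"))
  if (is.character(reads)) {
    reads <- tibble::tibble(seq = reads)
  }
  stopifnot(is.data.frame(reads), "seq" %in% names(reads))
  if (nrow(reads) == 0L) {
    return(dplyr::mutate(tibble::as_tibble(reads),
                         status = character(0), variant_dna = character(0),
                         variant_aa = character(0)))
  }
  seqs <- toupper(reads$seq)
  mm <- spec$max_flank_mismatch
  L <- spec$region_length

  locate_both <- function(s) {
    f5 <- .find_flank(s, spec$flank5, mm)
    # 3' flank searched downstream of the 5' hit
    rest_start <- f5$pos + nchar(spec$flank5)
    rest <- ifelse(is.na(f5$pos), NA_character_,
                   substr(s, rest_start, nchar(s)))
    f3 <- .find_flank(ifelse(is.na(rest), "", rest), spec$flank3, mm)
    list(p5 = f5$pos, gap = f3$pos - 1L, n5 = f5$nhit,
         start = rest_start)
  }

  fwd <- locate_both(seqs)
  found_fwd <- !is.na(fwd$p5) & !is.na(fwd$gap)
  # reverse-complement fallback for reads where the forward search failed
  rc_needed <- !found_fwd
  if (any(rc_needed)) {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[rc_needed])))
    seqs[rc_needed] <- rc
    rev <- locate_both(rc)
    fwd$p5[rc_needed] <- rev$p5
    fwd$gap[rc_needed] <- rev$gap
    fwd$n5[rc_needed] <- rev$n5
    fwd$start[rc_needed] <- rev$start
  }
  if (any(fwd$n5 > 1L, na.rm = TRUE)) {
    warning(sum(fwd$n5 > 1L, na.rm = TRUE),
            " read(s) with multiple 5' flank matches; leftmost used",
            call. = FALSE)
  }

  status <- rep("NO_FLANK", length(seqs))
  region <- rep(NA_character_, length(seqs))
  has_both <- !is.na(fwd$p5) & !is.na(fwd$gap)
  status[has_both & fwd$gap != L] <- "WRONG_LENGTH"
  ok_len <- has_both & fwd$gap == L
  region[ok_len] <- substr(seqs[ok_len], fwd$start[ok_len],
                           fwd$start[ok_len] + L - 1L)

  pat_ok <- rep(FALSE, length(seqs))
  if (any(ok_len)) {
    allowed <- .iupac[strsplit(spec$degeneracy_pattern, "")[[1]]]
    per_base <- rep(allowed, spec$n_variable_codons)
    mat <- matrix(TRUE, nrow = sum(ok_len), ncol = L)
    for (i in seq_len(L)) {
      mat[, i] <- grepl(sprintf("[%s]", per_base[i]),
                        substr(region[ok_len], i, i))
    }
    hit <- rowSums(mat) == L
    if (!is.null(spec$wildtype_dna)) {
      hit <- hit | region[ok_len] == spec$wildtype_dna
    }
    pat_ok[ok_len] <- hit
  }
  status[ok_len & !pat_ok] <- "NON_SNS"
  status[ok_len & pat_ok] <- "ACCEPTED"
  region[status != "ACCEPTED"] <- NA_character_

  aa <- rep(NA_character_, length(seqs))
  acc <- status == "ACCEPTED"
  if (any(acc)) {
    aa[acc] <- translate_region(region[acc])
    if (any(grepl("\\*", aa[acc]))) {
      # cannot occur for SNS (no SNS codon is a stop); guards other patterns
      stop("stop codon in accepted variable region", call. = FALSE)
    }
  }
  dplyr::mutate(tibble::as_tibble(reads),
                status = status, variant_dna = region, variant_aa = aa)
}

#' Count variants per phenotype pool
#'
#' Groups accepted variable regions at the amino-acid level (default, merging
#' synonymous codon variants — the level at which screen results are usually
#' reported) or at the DNA level, and counts reads per variant in each
#' phenotype pool. The result is the variant table on which ISPA detection
#' operates: variants seen in exactly one phenotype form the U set, variants
#' seen in both form the B set, and the total accepted read count N bounds
#' the per-variant counts (equality when no accepted read is discarded).
#'
#' @param regions A tibble with columns `phenotype`, `variant_dna`,
#'   `variant_aa` and optionally `status` (only `"ACCEPTED"` rows are
#'   counted), as produced by [extract_variable_region()].
#' @param level `"aa"` (default) or `"dna"`.
#' @return A tibble of class `"chispa_variants"` with columns `variant_aa`,
#'   `variant_dna` (`NA` at AA level), `wt_count`, `mut_count`, ordered by
#'   descending total count then variant; attributes `n_reads_total` and
#'   `level`. Use [variant_sets()] to annotate U/B membership.
#' @export
count_variants <- function(regions, level = c("aa", "dna")) {
  level <- match.arg(level)
  stopifnot(is.data.frame(regions),
            all(c("phenotype", "variant_aa") %in% names(regions)))
  if ("status" %in% names(regions)) {
    regions <- dplyr::filter(regions, .data$status == "ACCEPTED")
  }
  if (!all(regions$phenotype %in% c("WT", "MUT"))) {
    stop("phenotype must be WT or MUT", call. = FALSE)
  }
  n_total <- nrow(regions)
  grouped <- if (level == "dna") {
    dplyr::count(regions, .data$variant_dna, .data$variant_aa,
                 .data$phenotype)
  } else {
    dplyr::count(regions, .data$variant_aa, .data$phenotype)
  }
  tab <- tidyr::pivot_wider(grouped, names_from = "phenotype",
                            values_from = "n", values_fill = 0L)
  for (col in c("WT", "MUT")) if (!col %in% names(tab)) tab[[col]] <- 0L
  out <- tibble::tibble(
    variant_aa = tab$variant_aa,
    variant_dna = if (level == "dna") tab$variant_dna else
      rep(NA_character_, nrow(tab)),
    wt_count = as.integer(tab$WT),
    mut_count = as.integer(tab$MUT)
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$wt_count + .data$mut_count),
                        .data$variant_aa, .data$variant_dna)
  new_variant_table(out, n_reads_total = n_total, level = level)
}

new_variant_table <- function(tbl, n_reads_total, level) {
  stopifnot(all(c("variant_aa", "variant_dna", "wt_count", "mut_count")
                %in% names(tbl)))
  if (any(tbl$wt_count < 0L) || any(tbl$mut_count < 0L)) {
    stop("negative variant count", call. = FALSE)
  }
  if (nrow(tbl) > 0L && any(tbl$wt_count + tbl$mut_count < 1L)) {
    stop("variant with zero total count", call. = FALSE)
  }
  structure(tibble::as_tibble(tbl),
            n_reads_total = as.integer(n_reads_total),
            level = level,
            class = c("chispa_variants", class(tibble::tibble())))
}

#' Annotate U/B set membership of a variant table
#'
#' Adds a `set` column: `"U"` for variants observed in exactly one phenotype
#' pool, `"B"` for variants observed in both. Only B-set variants are testable
#' for incorrect sequence-phenotype assignment.
#'
#' @param table A variant table from [count_variants()] or
#'   [read_variant_table()].
#' @return The table with an added `set` column.
#' @export
variant_sets <- function(table) {
  dplyr::mutate(table,
                set = dplyr::if_else(.data$wt_count > 0L & .data$mut_count > 0L,
                                     "B", "U"))
}

#' Read / write a variant count table (TSV)
#'
#' Lossless round-trip of the phenotype-stratified variant counts in a fixed
#' four-column layout: `variant_aa`, `variant_dna` (empty at AA level),
#' `wt_count`, `mut_count`.
#'
#' @param table A variant table.
#' @param path File path.
#' @return `read_variant_table()` returns a `"chispa_variants"` tibble;
#'   `write_variant_table()` returns `path` invisibly.
#' @export
write_variant_table <- function(table, path) {
  readr::write_tsv(
    table[, c("variant_aa", "variant_dna", "wt_count", "mut_count")], path)
  invisible(path)
}

#' @rdname write_variant_table
#' @export
read_variant_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(),
                         progress = FALSE)
  missing <- setdiff(c("variant_aa", "wt_count", "mut_count"), names(tab))
  if (length(missing)) {
    stop("variant table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"variant_dna" %in% names(tab)) tab$variant_dna <- NA_character_
  tab$variant_aa <- as.character(tab$variant_aa)
  tab$variant_dna <- as.character(tab$variant_dna)
  tab$wt_count <- as.integer(tab$wt_count)
  tab$mut_count <- as.integer(tab$mut_count)
  level <- if (all(is.na(tab$variant_dna))) "aa" else "dna"
  new_variant_table(tab[, c("variant_aa", "variant_dna",
                            "wt_count", "mut_count")],
                    n_reads_total = sum(tab$wt_count) + sum(tab$mut_count),
                    level = level)
}
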