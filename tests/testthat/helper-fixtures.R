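# small in-code fixture builders shared across test files

write_fasta <- function(seqs, path = tempfile(fileext = ".fasta"),
                        ids = sprintf("r%d", seq_along(seqs))) {
  lines <- if (length(seqs)) as.vector(rbind(paste0(">", ids), seqs))
           else character(0)
  writeLines(lines, path)
  path
}

write_fastq <- function(seqs, path = tempfile(fileext = ".fastq"),
                        ids = sprintf("r%d", seq_along(seqs))) {
  lines <- if (length(seqs))
    as.vector(rbind(paste0("@", ids), seqs, "+", strrep("I", nchar(seqs))))
  else character(0)
  writeLines(lines, path)
  path
}

# a read with given variable region embedded in the default amplicon
make_read <- function(region, spec = amplicon_spec(),
                      pad5 = "AC", pad3 = "GT") {
  paste0(pad5, spec$flank5, region, spec$flank3, pad3)
}

# small screen config used where the full default scale is unnecessary
small_sim_config <- function(seed, ...) {
  sim_config(seed = seed, n_colonies_wt = 30L, n_colonies_mut = 80L,
             n_reads_total = 8000L,
             planted_true_ispas = list(
               list(dna = "ATTACCGCA", true_phenotype = "WT",
                    minority_rate = 0.28, depth = 400)),
             ...)
}

random_sns_region <- function(n) {
  cods <- degenerate_codon_table("SNS")$codon
  vapply(seq_len(n), function(i)
    paste(sample(cods, 3, replace = TRUE), collapse = ""), character(1))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
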