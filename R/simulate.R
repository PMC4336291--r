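#' Configure a synthetic saturation-mutagenesis screen
#'
#' The generator emulates the experimental design of an SNS-codon
#' saturation-mutagenesis screen read out by pooled amplicon sequencing:
#' two phenotype pools of colonies (wild-type phenotype, i.e. killed by the
#' toxin, and mutant phenotype, i.e. surviving), each colony carrying one
#' plasmid-borne variant of the three-codon variable region; a leaky
#' phenotypic selection that misassigns a colony's pool with probability
#' `leakiness`; per-base substitution sequencing errors; genomic-DNA decoy
#' reads spiked into the pools; and optionally planted cell-derived ISPAs —
#' variants whose reads genuinely appear in both pools at a rate far above
#' the error budget (the default plants the wild-type region at a 28%
#' minority rate and an expected depth of 1821 reads).
#'
#' @param seed Integer seed; mandatory (every stochastic path is seeded).
#' @param n_colonies_wt,n_colonies_mut Colonies per phenotype pool
#'   (defaults 246 and 699). Their sum must not exceed the number of
#'   amino-acid variants reachable under the degeneracy pattern (1000 for
#'   three SNS codons); each colony carries a distinct amino-acid variant.
#' @param n_reads_total Total amplicon reads across both pools (default
#'   1e5); decoy reads are added on top.
#' @param amplicon An [amplicon_spec()].
#' @param leakiness Probability a colony is assigned to the wrong pool
#'   (default 0.03).
#' @param e_seq Expected substitution errors per variable region per read
#'   (default 0.01); applied per base, uniformly over the region plus both
#'   flanks, so flank hits cause read rejection just as in real data.
#' @param planted_true_ispas List of planted cell-derived ISPAs, each a list
#'   with `dna` (region sequence), `true_phenotype` (`"WT"`/`"MUT"`),
#'   `minority_rate` (fraction of its reads assigned to the other pool) and
#'   optionally `depth` (expected read depth; defaults to the average).
#'   `NULL` disables planting; the default plants the wild-type region.
#' @param decoy_fraction Genomic-contamination reads as a fraction of
#'   `n_reads_total` (default 0.05); half the decoys lack the flanks, half
#'   carry flanks around a non-SNS region.
#' @param assay_plates,assay_colonies_per_plate Layout of the simulated
#'   leakiness assay (default 4 plates of 100 wild-type colonies).
#' @param depth_skew Log-normal sdlog of per-colony read-depth weights
#'   (default 0 = symmetric multinomial); positive values emulate PCR
#'   amplification bias.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(seed,
                       n_colonies_wt = 246L,
                       n_colonies_mut = 699L,
                       n_reads_total = 1e5,
                       amplicon = amplicon_spec(),
                       leakiness = 0.03,
                       e_seq = 0.01,
                       planted_true_ispas = list(
                         list(dna = "ATTACCGCA", true_phenotype = "WT",
                              minority_rate = 0.28, depth = 1821)),
                       decoy_fraction = 0.05,
                       assay_plates = 4L,
                       assay_colonies_per_plate = 100L,
                       depth_skew = 0) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot(inherits(amplicon, "amplicon_spec"),
            leakiness >= 0, leakiness <= 1, e_seq >= 0, e_seq <= 1,
            decoy_fraction >= 0, decoy_fraction < 1,
            n_colonies_wt >= 0, n_colonies_mut >= 0,
            n_colonies_wt + n_colonies_mut >= 1,
            n_reads_total >= 1, depth_skew >= 0)
  region_len <- amplicon$region_length
  for (p in planted_true_ispas) {
    stopifnot(is.list(p), !is.null(p$dna), !is.null(p$minority_rate))
    if (nchar(p$dna) != region_len) {
      stop("planted variant must be ", region_len, " nt", call. = FALSE)
    }
    stopifnot(p$minority_rate >= 0, p$minority_rate <= 1,
              p$true_phenotype %in% c("WT", "MUT"))
  }
  structure(list(
    seed = as.integer(seed),
    n_colonies_wt = as.integer(n_colonies_wt),
    n_colonies_mut = as.integer(n_colonies_mut),
    n_reads_total = as.integer(n_reads_total),
    amplicon = amplicon, leakiness = leakiness, e_seq = e_seq,
    planted_true_ispas = planted_true_ispas,
    decoy_fraction = decoy_fraction,
    assay_plates = as.integer(assay_plates),
    assay_colonies_per_plate = as.integer(assay_colonies_per_plate),
    depth_skew = depth_skew
  ), class = "sim_config")
}

# all amino-acid variants reachable under the pattern, as peptide strings
.reachable_peptides <- function(spec) {
  aas <- sort(unique(degenerate_codon_table(spec$degeneracy_pattern)$aa))
  aas <- setdiff(aas, "*")
  grid <- do.call(expand.grid,
                  c(rep(list(aas), spec$n_variable_codons),
                    list(stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)))
  do.call(paste0, grid)
}

# one random codon realisation per amino acid of a peptide
.random_dna_for <- function(peptides, spec) {
  tab <- degenerate_codon_table(spec$degeneracy_pattern)
  by_aa <- split(tab$codon, tab$aa)
  vapply(peptides, function(p) {
    aas <- strsplit(p, "")[[1]]
    paste(vapply(aas, function(a) {
      cods <- by_aa[[a]]
      cods[sample.int(length(cods), 1L)]
    }, character(1)), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# vectorised per-base substitution over fixed-length reads
.apply_substitutions <- function(reads, per_base_rate) {
  if (per_base_rate <= 0 || length(reads) == 0L) return(reads)
  len <- nchar(reads[1])
  n_mut <- stats::rbinom(length(reads), len, per_base_rate)
  idx <- which(n_mut > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(len, n_mut[i])
    s <- strsplit(reads[i], "")[[1]]
    for (p in pos) {
      s[p] <- sample(setdiff(bases, s[p]), 1L)
    }
    reads[i] <- paste(s, collapse = "")
  }
  reads
}

.random_seq <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n)
  apply(m, 1, paste, collapse = "")
}

#' Simulate a saturation-mutagenesis screen with known ground truth
#'
#' Generative steps: (1) draw a pool of distinct amino-acid variants and one
#' codon realisation per colony; (2) assign colonies their true phenotype
#' pools; (3) flip each colony's recorded pool with probability `leakiness`;
#' (4) add planted cell-derived ISPA colonies whose reads split across pools
#' at the configured minority rate; (5) draw per-colony read depths
#' (multinomial, optionally log-normally skewed); (6) apply per-base
#' substitution errors over the full read (flanks included), and append
#' decoy genomic-contamination reads. Identical seeds give identical output.
#'
#' @param config A [sim_config()].
#' @return A list of class `"sim_screen"`: `reads` (tibble `read_id`, `seq`,
#'   `phenotype` — the *recorded* pool), `colonies` (per-colony truth),
#'   `truth` (per-variant truth: `variant_aa`, `variant_dna`,
#'   `true_phenotype`, `true_ispa`, `planted`), `assay` (simulated leakiness
#'   assay, one row per plate) and `config`.
#' @examples
#' sim <- simulate_screen(sim_config(seed = 1, n_reads_total = 2000,
#'                                   n_colonies_wt = 20, n_colonies_mut = 50))
#' dplyr::count(sim$reads, phenotype)
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  spec <- config$amplicon
  n_col <- config$n_colonies_wt + config$n_colonies_mut

  pool <- .reachable_peptides(spec)
  planted <- config$planted_true_ispas
  if (n_col > length(pool)) {
    stop("more colonies (", n_col, ") than reachable amino-acid variants (",
         length(pool), ")", call. = FALSE)
  }
  if (length(planted) > length(pool)) {
    stop("more planted variants than the variant pool", call. = FALSE)
  }

  colony_aa <- sample(pool, n_col)
  colonies <- tibble::tibble(
    colony_id = sprintf("col%04d", seq_len(n_col)),
    variant_aa = colony_aa,
    variant_dna = .random_dna_for(colony_aa, spec),
    true_phenotype = rep(c("WT", "MUT"),
                         c(config$n_colonies_wt, config$n_colonies_mut)),
    planted = FALSE,
    minority_rate = 0
  )
  # phenotype-assignment error: colony recorded in the wrong pool
  flip <- stats::runif(n_col) < config$leakiness
  colonies$recorded_phenotype <- ifelse(
    flip, ifelse(colonies$true_phenotype == "WT", "MUT", "WT"),
    colonies$true_phenotype)

  if (length(planted) > 0L) {
    pl <- purrr::map_dfr(seq_along(planted), function(i) {
      p <- planted[[i]]
      tibble::tibble(
        colony_id = sprintf("planted%02d", i),
        variant_aa = translate_region(p$dna),
        variant_dna = p$dna,
        true_phenotype = p$true_phenotype,
        planted = TRUE,
        minority_rate = p$minority_rate,
        recorded_phenotype = p$true_phenotype)
    })
    colonies <- dplyr::bind_rows(colonies, pl)
  }

  # read depths: weight 1 per ordinary colony (optionally log-normal),
  # planted colonies weighted to hit their expected depth
  n_ord <- n_col
  w <- if (config$depth_skew > 0) {
    stats::rlnorm(n_ord, meanlog = 0, sdlog = config$depth_skew)
  } else rep(1, n_ord)
  if (length(planted) > 0L) {
    depths <- vapply(planted, function(p) {
      if (is.null(p$depth)) config$n_reads_total / (n_ord + length(planted))
      else as.numeric(p$depth)
    }, numeric(1))
    if (sum(depths) >= config$n_reads_total) {
      stop("planted depths exceed n_reads_total", call. = FALSE)
    }
    w_total <- sum(w) / (1 - sum(depths) / config$n_reads_total)
    w <- c(w, depths * w_total / config$n_reads_total)
  }
  depth <- as.integer(stats::rmultinom(1, config$n_reads_total,
                                       w / sum(w)))
  colonies$depth <- depth

  # expand to reads; planted colonies split across pools at minority_rate
  template <- paste0(spec$flank5, colonies$variant_dna, spec$flank3)
  pool_of <- rep(colonies$recorded_phenotype, depth)
  is_planted_read <- rep(colonies$planted, depth)
  if (any(is_planted_read)) {
    rates <- rep(colonies$minority_rate, depth)[is_planted_read]
    truth_pool <- pool_of[is_planted_read]
    to_minority <- stats::runif(sum(is_planted_read)) < rates
    pool_of[is_planted_read] <- ifelse(
      to_minority, ifelse(truth_pool == "WT", "MUT", "WT"), truth_pool)
  }
  reads <- rep(template, depth)
  per_base <- config$e_seq / spec$region_length
  reads <- .apply_substitutions(reads, per_base)

  # genomic-contamination decoys: half flankless, half flanked non-pattern
  n_decoy <- round(config$decoy_fraction * config$n_reads_total)
  decoy_seq <- character(0)
  if (n_decoy > 0L) {
    n_flankless <- n_decoy %/% 2L
    n_nonsns <- n_decoy - n_flankless
    read_len <- nchar(template[1])
    flankless <- .random_seq(n_flankless, read_len)
    region <- vapply(seq_len(n_nonsns), function(i) {
      repeat {
        r <- paste0(sample(c("A", "T"), 1L),
                    paste(sample(c("A", "C", "G", "T"),
                                 spec$region_length - 1L, replace = TRUE),
                          collapse = ""))
        if (is.null(spec$wildtype_dna) || r != spec$wildtype_dna) return(r)
      }
    }, character(1))
    nonsns <- paste0(spec$flank5, region, spec$flank3)
    decoy_seq <- c(flankless, nonsns)
    decoy_pool <- sample(c("WT", "MUT"), n_decoy, replace = TRUE)
    reads <- c(reads, decoy_seq)
    pool_of <- c(pool_of, decoy_pool)
  }

  ord <- sample.int(length(reads))   # shuffle pools together
  reads_tbl <- tibble::tibble(
    read_id = sprintf("read%07d", seq_along(reads)),
    seq = reads[ord],
    phenotype = pool_of[ord])

  truth <- colonies |>
    dplyr::group_by(.data$variant_aa) |>
    dplyr::summarise(
      variant_dna = .data$variant_dna[1],
      true_phenotype = .data$true_phenotype[1],
      true_ispa = any(.data$planted),
      planted = any(.data$planted),
      depth = sum(.data$depth), .groups = "drop")

  assay <- tibble::tibble(
    plate_id = sprintf("plate%d", seq_len(config$assay_plates)),
    colonies_total = config$assay_colonies_per_plate,
    survivors = stats::rbinom(config$assay_plates,
                              config$assay_colonies_per_plate,
                              config$leakiness))

  structure(list(reads = reads_tbl, colonies = colonies, truth = truth,
                 assay = assay, config = config),
            class = "sim_screen")
}

#' Write a simulated screen to disk
#'
#' Emits one 4-line FASTQ per phenotype pool (constant quality `"I"`), the
#' per-variant truth table and the leakiness assay as TSV.
#'
#' @param sim A [simulate_screen()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly. Files: `wt.fastq`, `mut.fastq`, `truth.tsv`,
#'   `assay.tsv`.
#' @export
write_screen <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_screen"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (pool in c("WT", "MUT")) {
    sub <- dplyr::filter(sim$reads, .data$phenotype == pool)
    qual <- strrep("I", nchar(sub$seq))
    lines <- as.vector(rbind(paste0("@", sub$read_id), sub$seq, "+", qual))
    writeLines(lines, file.path(dir, paste0(tolower(pool), ".fastq")))
  }
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  readr::write_tsv(sim$assay, file.path(dir, "assay.tsv"))
  invisible(dir)
}

#' Parameter-recovery experiment over replicated synthetic screens
#'
#' Runs the full pipeline (simulate, extract, count, calibrate the error
#' model from the simulated leakiness assay, classify) once per replicate
#' and scores the calls against the generator's ground truth: the
#' false-positive rate is the fraction of error-only B-set variants
#' (both-phenotype variants not planted as cell-derived ISPAs) called
#' TRUE_ISPA, and the power is the fraction of planted ISPAs recovered as
#' TRUE_ISPA. Replicate r uses seed `config$seed + r - 1`.
#'
#' @param config A [sim_config()].
#' @param replicates Number of replicates (0 gives an empty report).
#' @param alpha BiM test level (default 0.05).
#' @param conf Confidence level for the leakiness interval (default 0.95).
#' @param level Grouping level for [count_variants()] (default `"aa"`).
#' @param model Error model used for mu composition, `"bim"` (default) or
#'   `"bym"`.
#' @return A tibble with one row per replicate: `replicate`, `seed`, `mu`,
#'   `n_b_variants`, `n_error_b`, `false_true_rate`, `n_planted`,
#'   `n_recovered`, `power`, `budget_ok`.
#' @export
recovery_experiment <- function(config, replicates = 100, alpha = 0.05,
                                conf = 0.95, level = "aa",
                                model = c("bim", "bym")) {
  stopifnot(inherits(config, "sim_config"), replicates >= 0)
  model <- match.arg(model)
  if (replicates == 0L) {
    return(tibble::tibble(
      replicate = integer(0), seed = integer(0), mu = numeric(0),
      n_b_variants = integer(0), n_error_b = integer(0),
      false_true_rate = numeric(0), n_planted = integer(0),
      n_recovered = integer(0), power = numeric(0), budget_ok = logical(0)))
  }
  purrr::map_dfr(seq_len(replicates), function(r) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    sim <- simulate_screen(cfg)
    regions <- extract_variable_region(sim$reads, cfg$amplicon)
    tab <- count_variants(regions, level = level)
    em <- compose_mu(estimate_leakiness(sim$assay, conf = conf),
                     e_seq = cfg$e_seq, model = model)
    res <- classify_table(tab, em, alpha = alpha)
    planted_aa <- unique(vapply(cfg$planted_true_ispas,
                                function(p) translate_region(p$dna),
                                character(1)))
    calls <- res$calls
    the_call <- if (model == "bim") calls$bim_call else calls$bym_call
    err_b <- !(calls$variant_aa %in% planted_aa)
    rec <- calls$variant_aa %in% planted_aa & the_call == "TRUE_ISPA"
    tibble::tibble(
      replicate = r, seed = cfg$seed, mu = em$mu,
      n_b_variants = nrow(calls),
      n_error_b = sum(err_b),
      false_true_rate = if (any(err_b))
        mean(the_call[err_b] == "TRUE_ISPA") else 0,
      n_planted = length(planted_aa),
      n_recovered = sum(rec),
      power = if (length(planted_aa)) sum(rec) / length(planted_aa)
              else NA_real_,
      budget_ok = res$summary$budget_ok)
  })
}
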