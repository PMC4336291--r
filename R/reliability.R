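#' Parse a residue-position specification string
#'
#' Expands comma-separated positions and inclusive ranges the way such lists
#' are printed in the literature: `"2, 5, 22-29"` (hyphen, en-dash or em-dash)
#' with an optional trailing `"and"`. Deduplicates and sorts.
#'
#' @param text A single string.
#' @return Sorted integer vector of positions.
#' @examples
#' parse_position_spec("2, 5, 22-29, 31-33 and 97")
#' @export
parse_position_spec <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- gsub("–|—", "-", text)       # en/em dash -> hyphen
  text <- gsub("\\band\\b", ",", text)
  tokens <- trimws(strsplit(text, ",")[[1]])
  tokens <- tokens[nzchar(tokens)]
  out <- integer(0)
  for (tok in tokens) {
    if (grepl("^\\d+$", tok)) {
      out <- c(out, as.integer(tok))
    } else if (grepl("^\\d+\\s*-\\s*\\d+$", tok)) {
      ends <- as.integer(strsplit(tok, "-")[[1]])
      if (ends[2] < ends[1]) {
        stop("descending range: ", tok, call. = FALSE)
      }
      out <- c(out, seq(ends[1], ends[2]))
    } else {
      stop("cannot parse position token: '", tok, "'", call. = FALSE)
    }
  }
  sort(unique(out))
}

#' Define a set of known critical residues
#'
#' Critical residues are positions whose mutation abolishes protein function;
#' they are the positives against which critical-residue predictors are
#' scored.
#'
#' @param protein_id Identifier string.
#' @param protein_length Protein length L (integer >= 1).
#' @param positions Integer vector of 1-based critical positions, or a
#'   position-spec string for [parse_position_spec()].
#' @return An object of class `"critical_set"` with elements `protein_id`,
#'   `protein_length`, `positions`.
#' @examples
#' critical_residue_set("toy", 10, "1-3, 7")
#' @export
critical_residue_set <- function(protein_id, protein_length, positions) {
  if (is.character(positions)) positions <- parse_position_spec(positions)
  positions <- sort(unique(as.integer(positions)))
  protein_length <- as.integer(protein_length)
  stopifnot(protein_length >= 1L, length(positions) >= 1L)
  if (any(positions < 1L) || any(positions > protein_length)) {
    stop("positions must lie in [1, protein_length]", call. = FALSE)
  }
  structure(list(protein_id = protein_id,
                 protein_length = protein_length,
                 positions = positions),
            class = "critical_set")
}

#' @export
print.critical_set <- function(x, ...) {
  cat(sprintf("<critical_set> %s: %d/%d residues critical (%.3g%%)\n",
              x$protein_id, length(x$positions), x$protein_length,
              100 * length(x$positions) / x$protein_length))
  invisible(x)
}

#' Read a critical-residue set from a two-column TSV
#'
#' Expects columns `protein_id` and `position` (one row per critical
#' residue, a single protein per file).
#'
#' @param path File path.
#' @param protein_length Protein length L (not stored in the TSV).
#' @return A `"critical_set"`.
#' @export
read_critical_set <- function(path, protein_length) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    protein_id = readr::col_character(),
    position = readr::col_integer()))
  if (!all(c("protein_id", "position") %in% names(tab))) {
    stop("critical-set file needs columns protein_id, position",
         call. = FALSE)
  }
  ids <- unique(tab$protein_id)
  if (length(ids) != 1L) stop("expected a single protein_id", call. = FALSE)
  critical_residue_set(ids, protein_length, tab$position)
}

#' Confusion metrics of a ranked predictor at a top-k% threshold
#'
#' The predictor's top `ceiling(top_fraction * L)` ranked positions are
#' called positive; the rest negative. Metrics follow the usual definitions:
#' sensitivity TP/(TP+FN), specificity TN/(TN+FP), and the Matthews
#' correlation coefficient with the standard square-root denominator
#' (0 when the denominator vanishes, e.g. at `top_fraction = 1`).
#'
#' @param ranking A predictor ranking: integer vector of positions,
#'   best-first, or a tibble with a `position` column in rank order (see
#'   [read_predictor_ranking()]). A ranking covering only part of the protein
#'   is padded with the remaining positions in ascending order, with a
#'   warning.
#' @param criticals A [critical_residue_set()].
#' @param top_fraction Fraction(s) in (0, 1] of residues called positive.
#' @return A tibble with one row per threshold: `threshold`, `tp`, `tn`,
#'   `fp`, `fn`, `sensitivity`, `specificity`, `mcc`.
#' @examples
#' cs <- critical_residue_set("toy", 10, c(1, 2, 3))
#' confusion_at_threshold(c(1, 2, 4, 3, 5:10), cs, 0.3)
#' @export
confusion_at_threshold <- function(ranking, criticals, top_fraction) {
  stopifnot(inherits(criticals, "critical_set"),
            all(top_fraction > 0), all(top_fraction <= 1))
  L <- criticals$protein_length
  ranking <- .as_ranking_vector(ranking, L)
  pos <- criticals$positions
  purrr::map_dfr(top_fraction, function(t) {
    k <- ceiling(t * L)
    pred_pos <- ranking[seq_len(k)]
    tp <- sum(pred_pos %in% pos)
    fp <- k - tp
    fn <- length(pos) - tp
    tn <- L - k - fn
    denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
    mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
    tibble::tibble(threshold = t, tp = tp, tn = tn, fp = fp, fn = fn,
                   sensitivity = tp / (tp + fn),
                   specificity = tn / (tn + fp),
                   mcc = mcc)
  })
}

.as_ranking_vector <- function(ranking, L) {
  if (is.data.frame(ranking)) {
    stopifnot("position" %in% names(ranking))
    ranking <- ranking$position
  }
  ranking <- as.integer(ranking)
  if (anyDuplicated(ranking) || any(ranking < 1L) || any(ranking > L)) {
    stop("ranking must be distinct positions in [1, L]", call. = FALSE)
  }
  if (length(ranking) < L) {
    warning("ranking covers ", length(ranking), " of ", L,
            " positions; padding remainder in ascending order",
            call. = FALSE)
    ranking <- c(ranking, setdiff(seq_len(L), ranking))
  }
  ranking
}

#' Simulate incorrect critical-residue assignments (perturbation)
#'
#' Emulates the presence of ISPAs in a critical-residue list: a random
#' `fraction` of the known critical positions (round-half-even count) is
#' reassigned as negative, i.e. removed from the set. Uses the current RNG
#' state; seed with [set.seed()] for reproducibility. The input set is not
#' modified.
#'
#' @param criticals A [critical_residue_set()].
#' @param fraction Fraction in \[0, 1) of critical positions to drop
#'   (default 0.2).
#' @return A new `"critical_set"` with the reduced position set.
#' @export
perturb_criticals <- function(criticals, fraction = 0.2) {
  stopifnot(inherits(criticals, "critical_set"),
            fraction >= 0, fraction < 1)
  n_drop <- round(fraction * length(criticals$positions))
  if (n_drop == 0L) return(criticals)
  keep <- sort(sample(criticals$positions,
                      length(criticals$positions) - n_drop))
  critical_residue_set(criticals$protein_id, criticals$protein_length, keep)
}

#' Baseline predictors: perfect and random
#'
#' The perfect predictor ranks the known critical residues first (ascending
#' position) followed by the non-critical residues (ascending); the random
#' predictor is a uniform shuffle of all positions (current RNG state).
#'
#' @param criticals A [critical_residue_set()].
#' @return Integer vector of positions, best-first.
#' @export
perfect_predictor <- function(criticals) {
  stopifnot(inherits(criticals, "critical_set"))
  c(criticals$positions,
    setdiff(seq_len(criticals$protein_length), criticals$positions))
}

#' @rdname perfect_predictor
#' @param protein_length Protein length L.
#' @export
random_predictor <- function(protein_length) {
  sample.int(as.integer(protein_length))
}

#' Read a predictor ranking (TSV)
#'
#' Expects columns `rank` and `position`, optionally `score`. If `score` is
#' present the ranking is re-ordered by descending score with ties broken by
#' ascending position; otherwise rows are ordered by `rank`. External
#' predictors (e.g. conservation- or structure-based) are consumed this way;
#' they are never computed in-house.
#'
#' @param path File path.
#' @return A tibble with columns `rank`, `position` (and `score` if given),
#'   in final rank order.
#' @export
read_predictor_ranking <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols())
  if (!all(c("rank", "position") %in% names(tab))) {
    stop("ranking file needs columns rank, position", call. = FALSE)
  }
  tab <- if ("score" %in% names(tab)) {
    dplyr::arrange(tab, dplyr::desc(.data$score), .data$position)
  } else {
    dplyr::arrange(tab, .data$rank)
  }
  tab$rank <- seq_len(nrow(tab))
  tab
}

#' Reliability envelope of a predictor under ISPA perturbation
#'
#' Repeatedly perturbs the critical-residue set ([perturb_criticals()]) and
#' re-scores a fixed predictor ranking over a grid of top-k% thresholds,
#' collecting sensitivity, specificity and MCC per replicate. Metrics are
#' computed against the *perturbed* set by default — each replicate defines
#' its own "new critical residues" — with `score_against = "original"`
#' available for sensitivity analysis. Replicate 0 is the unperturbed
#' evaluation and is always included.
#'
#' @param ranking A predictor ranking (vector or tibble; see
#'   [confusion_at_threshold()]).
#' @param criticals A [critical_residue_set()].
#' @param fraction Fraction of criticals reassigned negative per replicate
#'   (default 0.2).
#' @param replicates Number of perturbation replicates (default 100).
#' @param thresholds Top-fraction grid (default `seq(0.05, 0.95, 0.05)`).
#' @param score_against `"perturbed"` (default) or `"original"`.
#' @param predictor Label stored in the output (default `"predictor"`).
#' @return An object of class `"reliability_envelope"`: a long tibble with
#'   columns `predictor`, `replicate` (0 = unperturbed), `threshold`,
#'   `sensitivity`, `specificity`, `mcc`; attribute `criticals`.
#' @examples
#' cs <- critical_residue_set("toy", 20, "1-6")
#' set.seed(1)
#' env <- reliability_envelope(perfect_predictor(cs), cs, replicates = 5)
#' @export
reliability_envelope <- function(ranking, criticals, fraction = 0.2,
                                 replicates = 100,
                                 thresholds = seq(0.05, 0.95, by = 0.05),
                                 score_against = c("perturbed", "original"),
                                 predictor = "predictor") {
  score_against <- match.arg(score_against)
  stopifnot(inherits(criticals, "critical_set"), replicates >= 0)
  ranking <- .as_ranking_vector(ranking, criticals$protein_length)
  one <- function(rep_id, cs) {
    dplyr::mutate(confusion_at_threshold(ranking, cs, thresholds),
                  replicate = rep_id, .before = 1)
  }
  rows <- list(one(0L, criticals))
  for (r in seq_len(replicates)) {
    pert <- perturb_criticals(criticals, fraction)
    scored <- if (score_against == "perturbed") pert else criticals
    rows[[r + 1L]] <- one(r, scored)
  }
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(predictor = predictor, .before = 1)
  structure(out, criticals = criticals,
            class = c("reliability_envelope", class(tibble::tibble())))
}

#' Per-threshold envelope summary (min / mean / max)
#'
#' @param x A `"reliability_envelope"`.
#' @param ... Unused.
#' @return A tibble with one row per predictor, threshold and metric:
#'   columns `predictor`, `threshold`, `metric`, `min`, `mean`, `max`
#'   (perturbation replicates only; the unperturbed replicate 0 is reported
#'   in `unperturbed`).
#' @export
tidy.reliability_envelope <- function(x, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(x),
                              c("sensitivity", "specificity", "mcc"),
                              names_to = "metric", values_to = "value")
  pert <- long |>
    dplyr::filter(.data$replicate > 0L) |>
    dplyr::group_by(.data$predictor, .data$threshold, .data$metric) |>
    dplyr::summarise(min = min(.data$value), mean = mean(.data$value),
                     max = max(.data$value), .groups = "drop")
  unpert <- long |>
    dplyr::filter(.data$replicate == 0L) |>
    dplyr::select("predictor", "threshold", "metric",
                  unperturbed = "value")
  out <- dplyr::left_join(unpert, pert,
                          by = c("predictor", "threshold", "metric"))
  # no perturbation replicates: envelope collapses onto the plain sweep
  dplyr::mutate(out,
                min = dplyr::coalesce(.data$min, .data$unperturbed),
                mean = dplyr::coalesce(.data$mean, .data$unperturbed),
                max = dplyr::coalesce(.data$max, .data$unperturbed))
}

#' Write a reliability envelope as long-format TSV
#'
#' Columns: `predictor`, `replicate`, `threshold`, `sensitivity`,
#' `specificity`, `mcc`.
#'
#' @param env A `"reliability_envelope"` (or a row-bound set of them).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_envelope <- function(env, path) {
  readr::write_tsv(tibble::as_tibble(env)[, c(
    "predictor", "replicate", "threshold",
    "sensitivity", "specificity", "mcc")], path)
  invisible(path)
}

#' Reliable region of a predictor
#'
#' The maximal contiguous run of thresholds where the predictor's envelope
#' minimum strictly exceeds the random predictor's envelope maximum for the
#' chosen metric: in that region the predictor is distinguishable from
#' chance despite the perturbation. Endpoints are members of the threshold
#' grid.
#'
#' @param predictor_env,random_env `"reliability_envelope"` objects on the
#'   same threshold grid.
#' @param metric `"sensitivity"` (default), `"specificity"` or `"mcc"`.
#' @return A one-row tibble `t_low`, `t_high`, `n_thresholds`, or a zero-row
#'   tibble if the envelopes overlap everywhere.
#' @export
reliable_region <- function(predictor_env, random_env,
                            metric = c("sensitivity", "specificity", "mcc")) {
  metric <- match.arg(metric)
  per <- function(env, fun) {
    tb <- tibble::as_tibble(env)
    if (any(tb$replicate > 0L)) {
      tb <- dplyr::filter(tb, .data$replicate > 0L)
    }
    tb |>
      dplyr::group_by(.data$threshold) |>
      dplyr::summarise(v = fun(.data[[metric]]), .groups = "drop") |>
      dplyr::arrange(.data$threshold)
  }
  lo <- per(predictor_env, min)
  hi <- per(random_env, max)
  if (!isTRUE(all.equal(lo$threshold, hi$threshold))) {
    stop("envelopes are on different threshold grids", call. = FALSE)
  }
  sep <- lo$v > hi$v
  if (!any(sep)) {
    return(tibble::tibble(t_low = numeric(0), t_high = numeric(0),
                          n_thresholds = integer(0)))
  }
  runs <- rle(sep)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  best <- which(runs$values)[which.max(runs$lengths[runs$values])]
  idx <- starts[best]:ends[best]
  tibble::tibble(t_low = lo$threshold[min(idx)],
                 t_high = lo$threshold[max(idx)],
                 n_thresholds = length(idx))
}

#' Is a predictor competent for a protein?
#'
#' A predictor is competent when its reliable region contains the protein's
#' known critical-residue fraction `|criticals| / L` — i.e. at the threshold
#' where the predictor would be asked to recover exactly the known critical
#' residues, it is still distinguishable from chance.
#'
#' @param region A [reliable_region()] result.
#' @param criticals A [critical_residue_set()].
#' @return Logical.
#' @export
competence <- function(region, criticals) {
  stopifnot(inherits(criticals, "critical_set"))
  if (nrow(region) == 0L) return(FALSE)
  frac <- length(criticals$positions) / criticals$protein_length
  frac >= region$t_low && frac <= region$t_high
}
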