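#' Search configuration for the profile domain scan
#'
#' Defaults mirror the published screen: E-value threshold 1e-10 and a
#' whole-protein length filter 350 < length < 650 (both strict).
#'
#' @param e_max E-value threshold (hits kept when `e_value < e_max`).
#' @param len_lo,len_hi strict protein-length bounds in residues.
#' @param n_shuffles residue shuffles per sequence used to calibrate the
#'   empirical null (>= 20).
#' @param seed integer seed controlling the shuffles.
#' @return object of class `search_config`.
#' @export
search_config <- function(e_max = 1e-10, len_lo = 350, len_hi = 650,
                          n_shuffles = 200, seed = 1L) {
  if (len_lo >= len_hi) stop("len_lo must be < len_hi")
  if (n_shuffles < 20) stop("n_shuffles must be >= 20")
  structure(list(e_max = e_max, len_lo = len_lo, len_hi = len_hi,
                 n_shuffles = as.integer(n_shuffles), seed = as.integer(seed)),
            class = "search_config")
}

#' Build an ungapped log-odds profile from a seed alignment
#'
#' Gap-majority columns are dropped. Per-column scores are
#' `log2((count + 1) / (n + 20) / background)` (Laplace-smoothed counts over
#' the 20 residues). The background is estimated from the alignment's
#' residue frequencies (Laplace-smoothed) unless supplied.
#'
#' @param seed_alignment character vector of aligned sequences (equal
#'   lengths; `-` for gaps).
#' @param background optional vector of 20 background probabilities in
#'   [AA_ALPHABET] order (must sum to 1).
#' @return object of class `profile_model`: list with `scores` (20 x L
#'   matrix, bits), `background`, `length`, `consensus`.
#' @export
build_profile <- function(seed_alignment, background = NULL) {
  if (length(seed_alignment) < 1) stop("need at least one aligned sequence")
  lens <- nchar(seed_alignment)
  if (length(unique(lens)) != 1) stop("ragged alignment: unequal sequence lengths")
  mat <- do.call(rbind, strsplit(seed_alignment, "", fixed = TRUE))
  ok_char <- mat %in% c(AA_ALPHABET, "-", ".")
  if (!all(ok_char)) {
    stop("alignment contains non-amino-acid characters: ",
         paste(unique(mat[!ok_char]), collapse = ", "))
  }
  is_gap <- mat == "-" | mat == "."
  keep <- colMeans(is_gap) <= 0.5
  if (!any(keep)) stop("all columns are gap-majority")
  mat <- mat[, keep, drop = FALSE]
  is_gap <- is_gap[, keep, drop = FALSE]

  if (is.null(background)) {
    res <- mat[!is_gap]
    cnt <- table(factor(res, levels = AA_ALPHABET))
    background <- as.numeric(cnt + 1) / (length(res) + 20)
  }
  if (length(background) != 20 || abs(sum(background) - 1) > 1e-9) {
    stop("background must be 20 probabilities summing to 1")
  }
  names(background) <- AA_ALPHABET

  L <- ncol(mat)
  scores <- matrix(0, nrow = 20, ncol = L,
                   dimnames = list(AA_ALPHABET, NULL))
  for (j in seq_len(L)) {
    col <- mat[, j]
    col <- col[!(col %in% c("-", "."))]
    cnt <- table(factor(col, levels = AA_ALPHABET))
    p <- (as.numeric(cnt) + 1) / (length(col) + 20)
    scores[, j] <- log2(p / background)
  }
  structure(list(scores = scores, background = background, length = L,
                 consensus = paste(AA_ALPHABET[apply(scores, 2, which.max)],
                                   collapse = "")),
            class = "profile_model")
}

#' Maximum attainable ungapped profile score
#'
#' Sum of the per-column maxima, in bits; the score of the profile's
#' consensus sequence.
#' @param profile a [build_profile()] model.
#' @return numeric scalar.
#' @export
profile_max_score <- function(profile) sum(apply(profile$scores, 2, max))

# upper-tail p-value of a Gumbel distribution fitted by moments to the
# shuffled-null best-window scores
gumbel_tail_p <- function(obs, null_scores) {
  m <- mean(null_scores)
  s <- stats::sd(null_scores)
  if (!is.finite(s) || s <= 0) {
    return(max(mean(null_scores >= obs), 1 / (length(null_scores) + 1)))
  }
  beta <- s * sqrt(6) / pi
  mu <- m - 0.57721566490153286 * beta
  z <- (obs - mu) / beta
  # P(X >= obs) = 1 - exp(-exp(-z)), stable for large z
  -expm1(-exp(-z))
}

#' Scan one protein with a profile
#'
#' Best ungapped window score over all placements of the profile along the
#' sequence. The significance is calibrated empirically: the sequence is
#' residue-shuffled `n_shuffles` times (seeded), an extreme-value (Gumbel)
#' distribution is fitted by moments to the shuffled best-window scores, and
#' the reported `e_value` is its upper-tail probability — the per-sequence
#' expected count of equal-or-better chance hits. Callers scanning a
#' proteome scale it by the number of sequences searched
#' (see [scan_proteome()]).
#'
#' @param profile a [build_profile()] model.
#' @param sequence protein sequence (character scalar).
#' @param config a [search_config()].
#' @param gene,species identifiers carried into the hit.
#' @return one-row data.frame (gene, species, score, e_value, start, end,
#'   protein_length; 0-based half-open coordinates), or `NULL` when the
#'   protein is shorter than the profile.
#' @export
scan_sequence <- function(profile, sequence, config = search_config(),
                          gene = NA_character_, species = NA_character_) {
  codes <- seq_codes(sequence)
  N <- length(codes)
  if (N < profile$length) return(NULL)
  obs <- cpp_best_window(codes, profile$scores)
  set.seed(config$seed)
  perms <- matrix(0L, nrow = config$n_shuffles, ncol = N)
  for (b in seq_len(config$n_shuffles)) perms[b, ] <- sample.int(N) - 1L
  null_scores <- cpp_null_scores(codes, profile$scores, perms)
  p <- gumbel_tail_p(obs$score, null_scores)
  data.frame(gene = gene, species = species, score = obs$score,
             e_value = p, start = obs$start, end = obs$start + profile$length,
             protein_length = N, stringsAsFactors = FALSE)
}

#' Scan a set of proteomes with a profile
#'
#' Runs [scan_sequence()] on every protein and scales the per-sequence tail
#' probabilities by the total number of sequences scanned, yielding
#' database-level E-values (expected false hits in the whole search).
#'
#' @param profile a [build_profile()] model.
#' @param proteomes named list (species -> named character vector of
#'   sequences), or a single named character vector.
#' @param config a [search_config()].
#' @return data.frame of hits (one row per scannable protein).
#' @export
scan_proteome <- function(profile, proteomes, config = search_config()) {
  if (is.character(proteomes)) proteomes <- list(unknown = proteomes)
  rows <- list()
  n_total <- sum(lengths(proteomes))
  for (sp in names(proteomes)) {
    seqs <- proteomes[[sp]]
    for (g in names(seqs)) {
      hit <- scan_sequence(profile, seqs[[g]], config, gene = g, species = sp)
      if (!is.null(hit)) rows[[length(rows) + 1L]] <- hit
    }
  }
  if (length(rows) == 0) {
    return(data.frame(gene = character(0), species = character(0),
                      score = numeric(0), e_value = numeric(0),
                      start = integer(0), end = integer(0),
                      protein_length = integer(0)))
  }
  hits <- do.call(rbind, rows)
  hits$e_value <- hits$e_value * n_total
  rownames(hits) <- NULL
  hits
}

#' Apply the significance and length screen to domain hits
#'
#' Keeps hits with `e_value < e_max` and `len_lo < protein_length < len_hi`
#' (all inequalities strict, matching the published screen); input order is
#' preserved and the operation is idempotent.
#'
#' @param hits data.frame of hits.
#' @param config a [search_config()].
#' @return filtered data.frame.
#' @export
filter_hits <- function(hits, config = search_config()) {
  if (nrow(hits) == 0) return(hits)
  keep <- hits$e_value < config$e_max &
    hits$protein_length > config$len_lo &
    hits$protein_length < config$len_hi
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Import an hmmsearch-style per-domain table
#'
#' Parses the whitespace-delimited `--domtblout` dialect. Lines starting
#' with `#` are skipped. The full-sequence E-value (column 7) is used as the
#' hit E-value (per-sequence convention); alignment coordinates (columns
#' 18-19, 1-based inclusive) are converted to 0-based half-open. Species is
#' parsed from `species|gene` target names when present.
#'
#' @param path file path.
#' @return data.frame of hits with the same columns as [scan_proteome()].
#' @export
read_domtbl <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  rows <- list()
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (grepl("^\\s*#", line) || grepl("^\\s*$", line)) next
    f <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(f) < 19) {
      stop("malformed domtbl row at line ", i, ": expected >= 19 fields")
    }
    num <- suppressWarnings(as.numeric(f[c(3, 7, 8, 18, 19)]))
    if (anyNA(num)) stop("malformed domtbl row at line ", i,
                         ": non-numeric field")
    target <- f[1]
    species <- NA_character_
    gene <- target
    if (grepl("|", target, fixed = TRUE)) {
      parts <- strsplit(target, "|", fixed = TRUE)[[1]]
      if (length(parts) == 2) {
        species <- parts[1]
        gene <- parts[2]
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene = gene, species = species, score = num[3], e_value = num[2],
      start = as.integer(num[4]) - 1L, end = as.integer(num[5]),
      protein_length = as.integer(num[1]), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(gene = character(0), species = character(0),
                      score = numeric(0), e_value = numeric(0),
                      start = integer(0), end = integer(0),
                      protein_length = integer(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export hits as TSV
#' @param hits data.frame of hits.
#' @param path output path.
#' @export
write_hits_tsv <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
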