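# Corpus preprocessing: canonicalize/deduplicate, prune rare tokens, apply a
# token-length quantile cutoff, encode with special tokens, split.

SPECIAL_TOKENS <- c(pad = "<", start = "!", end = "~")

#' Canonicalize and deduplicate a raw SMILES corpus
#'
#' Invalid strings (strict grammar check + molecular parser) are dropped and
#' counted; the survivors are canonicalized and deduplicated by canonical
#' form.  The result is sorted so it is independent of input order.
#'
#' @param entries Character vector of SMILES strings, or a data frame with a
#'   `smiles` column.
#' @return A tibble with one column `smiles` (unique canonical forms, sorted),
#'   with a `report` attribute: a one-row tibble of `n_input`, `n_invalid`,
#'   `n_duplicate`, `n_retained`.
#' @export
#' @examples
#' canonicalize_filter(c("CCO", "OCC", "C("))
canonicalize_filter <- function(entries) {
  if (is.data.frame(entries)) {
    assert_that("smiles" %in% names(entries), "need a `smiles` column")
    entries <- entries$smiles
  }
  entries <- as.character(entries)
  can <- canonical_smiles(entries)
  n_invalid <- sum(is.na(can))
  valid <- can[!is.na(can)]
  uniq <- sort(unique(valid))
  out <- tibble(smiles = uniq)
  attr(out, "report") <- report_row(
    n_input = length(entries),
    n_invalid = n_invalid,
    n_duplicate = length(valid) - length(uniq),
    n_retained = length(uniq)
  )
  out
}

#' Build a token vocabulary from a corpus
#'
#' The vocabulary holds the pad `<`, start `!` and end `~` specials at
#' indices 0, 1, 2, followed by the chemistry tokens of the corpus in sorted
#' order.  Indices are contiguous from 0.
#'
#' @param smiles Character vector (or tibble with `smiles`) of canonical
#'   SMILES.
#' @param min_count Occurrence floor recorded with the vocabulary (the floor
#'   is enforced by [prune_rare_tokens()], not here).
#' @return An object of class `token_vocabulary`.
#' @export
token_vocabulary <- function(smiles, min_count = 1L) {
  if (is.data.frame(smiles)) smiles <- smiles$smiles
  counts <- count_tokens(smiles)
  assert_that(!any(SPECIAL_TOKENS %in% counts$token),
              "corpus contains a reserved special token")
  chem <- sort(counts$token)
  tokens <- c(unname(SPECIAL_TOKENS), chem)
  structure(
    list(
      tokens = tokens,
      index = setNames(seq_along(tokens) - 1L, tokens),
      counts = counts,
      specials = SPECIAL_TOKENS,
      min_count = as.integer(min_count)
    ),
    class = "token_vocabulary"
  )
}

#' @export
print.token_vocabulary <- function(x, ...) {
  cat(sprintf("<token_vocabulary: %d tokens (3 specials + %d chemistry), min_count=%d>\n",
              length(x$tokens), length(x$tokens) - 3L, x$min_count))
  invisible(x)
}

#' @export
length.token_vocabulary <- function(x) length(x$tokens)

#' @rdname token_vocabulary
#' @param x A `token_vocabulary`.
#' @param ... Unused.
#' @method tidy token_vocabulary
#' @export
tidy.token_vocabulary <- function(x, ...) {
  tibble(token = x$tokens, index = unname(x$index[x$tokens])) %>%
    left_join(x$counts, by = "token")
}

#' Remove strings containing rare tokens
#'
#' Token occurrences are counted once over the input corpus; every string
#' containing at least one token whose count is below `min_count` is removed.
#' Counts are not recomputed after removal.
#'
#' @param corpus Tibble with a `smiles` column (canonical SMILES) or a
#'   character vector.
#' @param min_count Minimum corpus-wide occurrence count for a token to be
#'   kept (the full-scale default in the reference configuration is 1000).
#' @return A list with `corpus` (tibble of retained smiles), `vocabulary`
#'   (a [token_vocabulary()] built from the retained strings), and `report`
#'   (removed/retained counts and the removed token names).
#' @export
prune_rare_tokens <- function(corpus, min_count = 1000L) {
  assert_that(min_count >= 1, "min_count must be >= 1")
  if (is.data.frame(corpus)) corpus <- corpus$smiles
  counts <- count_tokens(corpus)
  rare <- counts$token[counts$count < min_count]
  if (length(corpus) == 0) {
    keep <- logical(0)
  } else if (length(rare) == 0) {
    keep <- rep(TRUE, length(corpus))
  } else {
    keep <- vapply(corpus, function(s) !any(tokenize_smiles(s) %in% rare),
                   logical(1), USE.NAMES = FALSE)
  }
  retained <- corpus[keep]
  if (length(retained) == 0) {
    rlang::warn("prune_rare_tokens: all strings removed")
  }
  list(
    corpus = tibble(smiles = retained),
    vocabulary = token_vocabulary(retained, min_count = min_count),
    report = list(
      n_input = length(corpus),
      n_removed = sum(!keep),
      n_retained = sum(keep),
      removed_tokens = rare,
      n_tokens_before = nrow(counts),
      n_tokens_after = nrow(counts) - length(rare)
    )
  )
}

#' Token-length quantile cutoff
#'
#' Finds the smallest length `L` such that at least `coverage` of the corpus
#' has token length `<= L`, and removes all longer strings.  Lengths are
#' measured in tokens, not characters.
#'
#' @param corpus Tibble with `smiles` or character vector.
#' @param coverage Fraction of the corpus the cutoff must cover (the
#'   full-scale default in the reference configuration is 0.9999).
#' @return List with `cutoff` (integer length) and `corpus` (tibble of
#'   retained smiles).
#' @export
length_cutoff <- function(corpus, coverage = 0.9999) {
  assert_that(coverage > 0 && coverage <= 1, "coverage must be in (0, 1]")
  if (is.data.frame(corpus)) corpus <- corpus$smiles
  assert_that(length(corpus) > 0, "length_cutoff: empty corpus")
  lens <- vapply(corpus, function(s) length(tokenize_smiles(s)), integer(1),
                 USE.NAMES = FALSE)
  cands <- sort(unique(lens))
  frac <- vapply(cands, function(L) mean(lens <= L), numeric(1))
  cutoff <- cands[which(frac >= coverage)[1]]
  list(cutoff = as.integer(cutoff),
       corpus = tibble(smiles = corpus[lens <= cutoff]))
}

#' Encode a SMILES string as an index sequence
#'
#' The sequence is `start + tokens + end + pads`, always of total length
#' `max_len + 2`.  Indices are the 0-based vocabulary indices.
#'
#' @param smiles A single SMILES string.
#' @param vocabulary A [token_vocabulary()].
#' @param max_len Maximum token length (sequences are `max_len + 2` long).
#' @return Integer vector of length `max_len + 2`.
#' @export
encode_smiles <- function(smiles, vocabulary, max_len) {
  tokens <- tokenize_smiles(smiles)
  assert_that(length(tokens) <= max_len,
              sprintf("SMILES has %d tokens, exceeds max_len %d",
                      length(tokens), max_len))
  unknown <- setdiff(tokens, vocabulary$tokens)
  assert_that(length(unknown) == 0,
              paste0("tokens not in vocabulary: ",
                     paste(unique(unknown), collapse = " ")))
  sp <- vocabulary$specials
  idx <- unname(vocabulary$index[c(sp[["start"]], tokens, sp[["end"]])])
  c(idx, rep(unname(vocabulary$index[sp[["pad"]]]),
             max_len + 2L - length(idx)))
}

#' Decode an index sequence back to a SMILES string
#'
#' Inverts [encode_smiles()]: strips the start token, reads up to the first
#' end token, and concatenates.  Returns `NA` if the sequence is malformed
#' (no start prefix or no end token).
#'
#' @param indices Integer vector of 0-based vocabulary indices.
#' @param vocabulary A [token_vocabulary()].
#' @return A single SMILES string, or `NA_character_`.
#' @export
decode_sequence <- function(indices, vocabulary) {
  sp <- vocabulary$specials
  start_i <- unname(vocabulary$index[sp[["start"]]])
  end_i <- unname(vocabulary$index[sp[["end"]]])
  if (length(indices) == 0 || indices[1] != start_i) return(NA_character_)
  body <- indices[-1]
  stop_at <- which(body == end_i)
  if (length(stop_at) == 0) return(NA_character_)
  body <- body[seq_len(stop_at[1] - 1)]
  if (length(body) == 0) return("")
  paste(vocabulary$tokens[body + 1L], collapse = "")
}

# Vectorised decoding of a whole matrix of sampled index sequences: map ids
# to tokens, blank everything at/after the first end token, paste columns.
decode_sequences <- function(ids, vocabulary) {
  sp <- vocabulary$specials
  start_i <- unname(vocabulary$index[sp[["start"]]])
  end_i <- unname(vocabulary$index[sp[["end"]]])
  n <- nrow(ids)
  if (n == 0) return(character(0))
  has_start <- !is.na(ids[, 1]) & ids[, 1] == start_i
  body <- ids[, -1, drop = FALSE]
  is_end <- !is.na(body) & body == end_i
  # first end position per row (Inf when none)
  poss <- lapply(seq_len(ncol(body)), function(j) ifelse(is_end[, j], j, Inf))
  first_end <- do.call(pmin, poss)
  toks <- matrix(vocabulary$tokens[body + 1L], n)
  keep <- col(body) < first_end
  toks[!keep | is.na(toks)] <- ""
  out <- do.call(paste0, lapply(seq_len(ncol(toks)), function(j) toks[, j]))
  out[!has_start | !is.finite(first_end)] <- NA_character_
  out
}

#' Encode a whole corpus
#'
#' @param corpus Tibble with `smiles` or character vector; every string must
#'   have token length `<= max_len`.
#' @param vocabulary A [token_vocabulary()].
#' @param max_len Token-length cutoff (e.g. from [length_cutoff()]).
#' @return An `encoded_corpus`: integer matrix (`n x (max_len + 2)`) of
#'   0-based indices with attributes `vocabulary`, `max_len` and row names
#'   equal to the SMILES.
#' @export
encode_corpus <- function(corpus, vocabulary, max_len) {
  if (is.data.frame(corpus)) corpus <- corpus$smiles
  mat <- t(vapply(corpus, encode_smiles, integer(max_len + 2L),
                  vocabulary = vocabulary, max_len = max_len))
  rownames(mat) <- corpus
  structure(mat, vocabulary = vocabulary, max_len = as.integer(max_len),
            class = c("encoded_corpus", class(mat)))
}

#' Random train/validation split
#'
#' Train size is `floor(train_fraction * n)`; the remainder goes to
#' validation.  The partition is reproducible under a fixed seed.
#'
#' @param corpus Tibble with `smiles` or character vector.
#' @param train_fraction Fraction assigned to training (default 0.95).
#' @param seed Integer seed.
#' @return List with tibbles `train` and `validation`.
#' @export
split_corpus <- function(corpus, train_fraction = 0.95, seed = 1L) {
  if (is.data.frame(corpus)) corpus <- corpus$smiles
  n <- length(corpus)
  assert_that(n >= 2, "split_corpus: need at least 2 strings")
  assert_that(train_fraction > 0 && train_fraction < 1,
              "train_fraction must be in (0, 1)")
  n_train <- floor(train_fraction * n)
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = tibble(smiles = corpus[sort(idx)]),
       validation = tibble(smiles = corpus[sort(setdiff(seq_len(n), idx))]))
}

#' Full corpus preprocessing pipeline
#'
#' Canonicalize/deduplicate, prune rare tokens, apply the length cutoff,
#' build the vocabulary, encode, and split.
#'
#' @param entries Raw SMILES (character vector or tibble with `smiles`).
#' @param min_count Token occurrence floor for [prune_rare_tokens()].
#' @param coverage Length-cutoff coverage for [length_cutoff()].
#' @param train_fraction Training fraction for [split_corpus()].
#' @param seed Integer seed for the split.
#' @return List with `vocabulary`, `max_len`, `train`/`validation` encoded
#'   corpora, `corpus` (the retained canonical smiles tibble) and `report`.
#' @export
preprocess_corpus <- function(entries, min_count = 1L, coverage = 0.9999,
                              train_fraction = 0.95, seed = 1L) {
  can <- canonicalize_filter(entries)
  pruned <- prune_rare_tokens(can, min_count = min_count)
  cut <- length_cutoff(pruned$corpus, coverage = coverage)
  vocab <- pruned$vocabulary
  enc <- function(x) encode_corpus(x, vocab, cut$cutoff)
  sp <- split_corpus(cut$corpus, train_fraction, seed)
  list(
    vocabulary = vocab,
    max_len = cut$cutoff,
    train = enc(sp$train),
    validation = enc(sp$validation),
    corpus = cut$corpus,
    report = list(
      canonicalize = attr(can, "report"),
      prune = pruned$report,
      cutoff = cut$cutoff,
      n_train = nrow(sp$train),
      n_validation = nrow(sp$validation),
      toolkit = toolkit_versions()
    )
  )
}

#' @importFrom dplyr %>%
#' @export
dplyr::`%>%`
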