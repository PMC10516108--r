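# SMILES token grammar.
#
# The grammar recognises bracket atoms as single tokens, the two-letter
# organic-subset halogens Cl and Br, single-letter organic-subset and
# aromatic atoms, ring-bond digits and %nn ring closures, bond symbols,
# branches and the dot disconnect.  Concatenating the tokens of a string
# reproduces it exactly.

.SMILES_SINGLE <- c("B", "C", "N", "O", "P", "S", "F", "I",
                    "b", "c", "n", "o", "p", "s",
                    "(", ")", "-", "=", "#", "$", ":", "/", "\\", ".", "*",
                    as.character(0:9))

#' Tokenize a SMILES string
#'
#' Splits a SMILES string into chemically meaningful tokens: bracket atoms
#' (`[nH]`, `[O-]`, ...) and two-letter halogens (`Cl`, `Br`) are single
#' tokens; everything else follows the standard one-character grammar
#' (organic-subset atoms, aromatic atoms, bonds, branches, ring-bond digits
#' and `%nn` two-digit ring closures).
#'
#' @param smiles A single SMILES string.
#' @return Character vector of tokens whose concatenation equals `smiles`.
#' @export
#' @examples
#' tokenize_smiles("CC(=O)Oc1ccccc1Cl")
.SMILES_PATTERN <- "\\[[^][]*\\]|%[0-9]{2}|Cl|Br|."

# Vectorised tokenizer core: one regex pass over a character vector.
# Returns a list of token vectors; tokens failing validation are flagged by
# an "invalid_at" attribute (first bad token index) on the element.
tokenize_many <- function(smiles) {
  toks <- regmatches(smiles, gregexpr(.SMILES_PATTERN, smiles, perl = TRUE))
  lapply(toks, function(tk) {
    known <- tk %in% .SMILES_SINGLE | tk %in% c("Cl", "Br") |
      startsWith(tk, "%") |
      (startsWith(tk, "[") & endsWith(tk, "]") & nchar(tk) > 2)
    if (!all(known)) attr(tk, "invalid_at") <- which(!known)[1]
    tk
  })
}

tokenize_smiles <- function(smiles) {
  assert_that(is.character(smiles) && length(smiles) == 1,
              "tokenize_smiles() expects a single string")
  if (nchar(smiles) == 0) return(character(0))
  tk <- tokenize_many(smiles)[[1]]
  bad <- attr(tk, "invalid_at")
  if (!is.null(bad)) {
    offset <- if (bad == 1) 1L else sum(nchar(tk[seq_len(bad - 1)])) + 1L
    rlang::abort(sprintf("unrecognised token '%s' at offset %d in '%s'",
                         tk[bad], offset, smiles))
  }
  as.character(tk)
}

# Strict syntactic well-formedness: tokenizable, balanced parentheses, every
# ring-closure label paired.  OpenBabel alone is too lenient here (it will
# happily parse "C(" as methane), so this check runs first.
smiles_syntax_ok_tokens <- function(tokens) {
  if (length(tokens) == 0 || !is.null(attr(tokens, "invalid_at"))) return(FALSE)
  depth <- 0
  ring_open <- character(0)
  for (tk in tokens) {
    if (tk == "(") depth <- depth + 1
    else if (tk == ")") {
      depth <- depth - 1
      if (depth < 0) return(FALSE)
    } else if (nchar(tk) == 1 && tk >= "0" && tk <= "9" || startsWith(tk, "%")) {
      lab <- sub("^%", "", tk)
      if (lab %in% ring_open) ring_open <- setdiff(ring_open, lab)
      else ring_open <- c(ring_open, lab)
    }
  }
  depth == 0 && length(ring_open) == 0
}

smiles_syntax_ok <- function(smiles) {
  vapply(tokenize_many(smiles), smiles_syntax_ok_tokens, logical(1))
}

#' Count token occurrences across a corpus
#'
#' @param smiles Character vector of SMILES strings.
#' @return A tibble with columns `token` and `count`, sorted by decreasing
#'   count.
#' @export
count_tokens <- function(smiles) {
  many <- tokenize_many(smiles)
  bad <- which(vapply(many, function(t) !is.null(attr(t, "invalid_at")), logical(1)))
  if (length(bad) > 0) tokenize_smiles(smiles[bad[1]])  # raise the error
  tk <- unlist(many, use.names = FALSE)
  if (length(tk) == 0) return(tibble(token = character(0), count = integer(0)))
  tab <- sort(table(tk), decreasing = TRUE)
  tibble(token = names(tab), count = as.integer(tab))
}
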