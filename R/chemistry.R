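# Thin wrappers around the OpenBabel-backed chemistry toolkit
# (ChemmineR / ChemmineOB): batch canonicalization, validity, SDF conversion.
# All higher modules go through these so the toolkit dialect is recorded in
# one place.

#' Canonicalize SMILES strings in batch
#'
#' Returns the toolkit's canonical SMILES for each input, or `NA` for strings
#' that fail either the strict syntax check (token grammar, balanced
#' branches, paired ring closures) or the molecular parser.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of the same length; `NA` where invalid.
#' @export
#' @examples
#' canonical_smiles(c("OCC", "C(", "c1ccccc1"))
canonical_smiles <- function(smiles) {
  n <- length(smiles)
  if (n == 0) return(character(0))
  out <- rep(NA_character_, n)
  idx <- which(smiles_syntax_ok(smiles))
  if (length(idx) == 0) return(out)
  tagged <- paste(smiles[idx], paste0("t", seq_along(idx)))
  res <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", paste(tagged, collapse = "\n")),
    error = function(e) ""
  )
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2) next
    tag <- trimws(parts[2])
    can <- trimws(parts[1])
    k <- suppressWarnings(as.integer(sub("^t", "", tag)))
    if (!is.na(k) && k >= 1 && k <= length(idx) && nzchar(can)) {
      out[idx[k]] <- can
    }
  }
  out
}

#' Test SMILES validity
#'
#' A string is valid when it passes the strict token-grammar/balance check
#' and the molecular parser accepts it.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Logical vector.
#' @export
is_valid_smiles <- function(smiles) {
  !is.na(canonical_smiles(smiles))
}

# Parse SMILES into an SDFset (3D-free connectivity tables).  Invalid inputs
# are dropped; names are preserved on the retained set.
smiles_to_sdf <- function(smiles, names = NULL) {
  if (is.null(names)) names <- paste0("m", seq_along(smiles))
  stopifnot(length(names) == length(smiles))
  x <- setNames(smiles, names)
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(x))
  keep <- suppressWarnings(ChemmineR::validSDF(sdf))
  sdf[keep]
}

# Memoised canonicalization for the generation loop: generated strings recur
# heavily across sampling rounds and iterations, and parser calls dominate
# otherwise.  The memo is capped to bound memory.
.canon_memo <- new.env(parent = emptyenv())

canonical_smiles_memo <- function(smiles, cap = 500000L) {
  out <- rep(NA_character_, length(smiles))
  known <- vapply(smiles, function(s) exists(s, envir = .canon_memo),
                  logical(1), USE.NAMES = FALSE)
  if (any(known)) {
    out[known] <- vapply(smiles[known], get, character(1),
                         envir = .canon_memo, USE.NAMES = FALSE)
  }
  fresh <- unique(smiles[!known])
  if (length(fresh) > 0) {
    fc <- canonical_smiles(fresh)
    if (length(ls(.canon_memo)) + length(fresh) <= cap) {
      for (i in seq_along(fresh)) assign(fresh[i], fc[i], envir = .canon_memo)
    }
    out[!known] <- fc[match(smiles[!known], fresh)]
  }
  out
}

toolkit_versions <- function() {
  list(
    ChemmineR = as.character(utils::packageVersion("ChemmineR")),
    ChemmineOB = as.character(utils::packageVersion("ChemmineOB"))
  )
}
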