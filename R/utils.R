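# Internal helpers shared across modules: seed derivation, SMILES file I/O,
# small assertions.

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) rlang::abort(msg, class = "chemalign_error")
  invisible(TRUE)
}

#' Derive a per-stage, per-iteration seed from a master seed
#'
#' Every source of randomness in a run draws its seed from the master seed
#' through this function, so any stage of any iteration can be reproduced in
#' isolation.  The derivation is a fixed integer hash (multiply-accumulate of
#' the stage name's character codes with the master seed and iteration index,
#' reduced modulo 2^31 - 1) and is documented so external tooling can
#' recompute it.
#'
#' @param master_seed Integer master seed for the run.
#' @param stage Character stage label, e.g. `"generate"`, `"cluster"`.
#' @param iteration Iteration index (0 = the post-pretraining generation).
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1L, "generate", 0)
derive_seed <- function(master_seed, stage, iteration = 0L) {
  assert_that(is.numeric(master_seed) && length(master_seed) == 1,
              "master_seed must be a single integer")
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- (as.double(master_seed) %% m)
  for (code in utf8ToInt(stage)) {
    h <- (h * 131 + code) %% m
  }
  h <- (h * 131 + as.double(iteration) + 17) %% m
  as.integer(h %% (m - 2) + 1)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Read SMILES strings from a file
#'
#' Accepts plain text (one SMILES per line, optionally followed by a
#' whitespace-separated name) or CSV with a `smiles` column.  Gzip-compressed
#' files are handled transparently.
#'
#' @param path Path to a `.smi`/`.txt`/`.csv` file (optionally `.gz`).
#' @return A tibble with columns `smiles` and `name`.
#' @export
read_smiles <- function(path) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  stripped <- sub("\\.gz$", "", path)
  if (grepl("\\.csv$", stripped, ignore.case = TRUE)) {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    assert_that("smiles" %in% names(df), "CSV input must have a `smiles` column")
    nm <- if ("name" %in% names(df)) as.character(df$name) else paste0("mol", seq_len(nrow(df)))
    return(tibble(smiles = as.character(df$smiles), name = nm))
  }
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[ \t]+")
  tibble(
    smiles = map_chr(parts, 1),
    name = imap_chr2(parts, function(p, i) if (length(p) > 1) p[[2]] else paste0("mol", i))
  )
}

imap_chr2 <- function(x, f) {
  vapply(seq_along(x), function(i) f(x[[i]], i), character(1))
}

#' Write SMILES strings to a plain-text file
#'
#' @param x Character vector of SMILES, or a tibble with a `smiles` column
#'   (and optionally `name`).
#' @param path Output path; `.gz` suffix triggers compression.
#' @return `path`, invisibly.
#' @export
write_smiles <- function(x, path) {
  if (is_tibble(x) || is.data.frame(x)) {
    assert_that("smiles" %in% names(x), "need a `smiles` column")
    lines <- if ("name" %in% names(x)) paste(x$smiles, x$name) else x$smiles
  } else {
    lines <- as.character(x)
  }
  readr::write_lines(lines, path)
  invisible(path)
}

# Named numeric vector -> one-row tibble (used for reports)
report_row <- function(...) as_tibble(as.list(c(...)))
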