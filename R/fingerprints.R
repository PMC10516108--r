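# Molecular fingerprints for similarity metrics: a circular (Morgan,
# radius 2, ECFP4-equivalent) fingerprint computed from the connectivity
# table, and the toolkit's path-based fingerprint.  Both are exposed as bit
# sets so the Tanimoto coefficient is a plain set computation.

# deterministic integer hash of an integer vector (31-bit)
hash_ints <- function(v) {
  h <- 17
  for (x in v) h <- (h * 31 + (x %% 2147483647)) %% 2147483647
  as.integer(h)
}

# Morgan/circular fingerprint of one SDF component: iteratively hash each
# atom's neighbourhood out to `radius` bonds; every intermediate identifier
# sets one bit.
morgan_bits_sdf <- function(sdf_mol, radius = 2L, n_bits = 2048L) {
  ab <- ChemmineR::atomblock(sdf_mol)
  bb <- ChemmineR::bondblock(sdf_mol)
  el <- gsub("_.*$", "", rownames(ab))
  n <- nrow(ab)
  nb <- vector("list", n)
  border <- list()
  if (!is.null(bb) && nrow(bb) > 0) {
    for (r in seq_len(nrow(bb))) {
      i <- bb[r, 1]; j <- bb[r, 2]; o <- bb[r, 3]
      nb[[i]] <- rbind(nb[[i]], c(j, o))
      nb[[j]] <- rbind(nb[[j]], c(i, o))
    }
  }
  # initial invariant: element, degree, aromatic-bond participation
  elem_code <- match(el, names(VDW_RADII), nomatch = 99L)
  deg <- vapply(nb, function(x) if (is.null(x)) 0L else nrow(x), integer(1))
  arom <- vapply(nb, function(x) if (is.null(x)) 0L else sum(x[, 2] == 4),
                 integer(1))
  inv <- mapply(function(e, d, a) hash_ints(c(e, d, a)),
                elem_code, deg, arom)
  ids <- inv
  for (r in seq_len(radius)) {
    inv_new <- integer(n)
    for (i in seq_len(n)) {
      if (is.null(nb[[i]])) {
        inv_new[i] <- hash_ints(c(r, inv[i]))
      } else {
        pairs <- cbind(nb[[i]][, 2], inv[nb[[i]][, 1]])
        pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
        inv_new[i] <- hash_ints(c(r, inv[i], as.vector(t(pairs))))
      }
    }
    inv <- inv_new
    ids <- c(ids, inv)
  }
  sort(unique(ids %% n_bits))
}

#' Fingerprint molecules as bit sets
#'
#' @param smiles Character vector of SMILES.
#' @param kind `"circular"` (Morgan radius 2, an ECFP4-equivalent, 2048
#'   bits) or `"path"` (the toolkit's path-based FP2, 1024 bits).
#' @return Named list of sorted integer vectors (set bit positions);
#'   entries are `NULL` for molecules that could not be fingerprinted.
#' @export
fingerprint_bits <- function(smiles, kind = c("circular", "path")) {
  kind <- match.arg(kind)
  nm <- paste0("f", seq_along(smiles))
  sdf <- tryCatch(smiles_to_sdf(smiles, nm), error = function(e) NULL)
  out <- setNames(vector("list", length(smiles)), smiles)
  if (is.null(sdf) || length(sdf) == 0) return(out)
  idx <- match(ChemmineR::sdfid(sdf), nm)
  if (kind == "circular") {
    for (i in seq_along(idx)) {
      out[[idx[i]]] <- morgan_bits_sdf(sdf[[i]])
    }
  } else {
    fp <- ChemmineR::fingerprintOB(sdf, "FP2")
    m <- methods::slot(fp, "fpma")
    for (i in seq_along(idx)) {
      out[[idx[i]]] <- which(m[i, ] != 0)
    }
  }
  out
}

#' Tanimoto coefficient between bit sets
#'
#' `|A intersect B| / |A union B|`; 1 when both sets are empty.
#'
#' @param a,b Integer vectors of set bit positions.
#' @return Numeric in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}
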