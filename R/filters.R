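# Configurable drug-likeness and functional-group filtering of generated
# molecules: ordered named rules, each either a numeric property bound or a
# SMARTS substructure allow/deny pattern.

#' Build a filter set
#'
#' A filter set is an ordered list of named predicates.  A molecule is
#' retained iff it passes every rule; a rejection is attributed to the
#' first failing rule.  Two rule shapes exist:
#'
#' * property bound: `list(property = "MW", min = 0, max = 500)` — the
#'   property is a toolkit-computed value (`MW`, `logP`, `TPSA`, `HBD`,
#'   `HBA`, `MR`);
#' * substructure: `list(pattern = "[N+](=O)[O-]", action = "deny")`
#'   (or `"allow"`, requiring a match).
#'
#' Patterns are validated at load time, not per molecule.
#'
#' @param rules Named list of rules as above, or a path to a YAML file with
#'   a top-level `rules:` mapping.
#' @return A `filter_set`.
#' @export
filter_set <- function(rules = list()) {
  if (is.character(rules)) {
    cfg <- yaml::read_yaml(rules)
    rules <- cfg$rules %||% cfg
  }
  assert_that(length(rules) == 0 || !is.null(names(rules)),
              "rules must be named")
  assert_that(!anyDuplicated(names(rules)), "rule names must be unique")
  props <- c("MW", "logP", "TPSA", "HBD", "HBA", "MR")
  for (nm in names(rules)) {
    r <- rules[[nm]]
    if (!is.null(r$property)) {
      assert_that(r$property %in% props,
                  paste0("rule ", nm, ": unknown property ", r$property))
      r$min <- r$min %||% -Inf
      r$max <- r$max %||% Inf
      assert_that(r$min <= r$max, paste0("rule ", nm, ": min > max"))
    } else if (!is.null(r$pattern)) {
      r$action <- r$action %||% "deny"
      assert_that(r$action %in% c("deny", "allow"),
                  paste0("rule ", nm, ": action must be deny or allow"))
      ok <- tryCatch({
        sdf <- smiles_to_sdf("CCO")
        ChemmineOB::smartsSearch_OB(ChemmineR::obmol(sdf[1]), r$pattern)
        TRUE
      }, error = function(e) FALSE)
      assert_that(ok, paste0("rule ", nm, ": malformed pattern ", r$pattern))
    } else {
      rlang::abort(paste0("rule ", nm, ": need `property` or `pattern`"))
    }
    rules[[nm]] <- r
  }
  structure(list(rules = rules), class = "filter_set")
}

#' @export
print.filter_set <- function(x, ...) {
  cat(sprintf("<filter_set: %d rule(s): %s>\n", length(x$rules),
              paste(names(x$rules), collapse = ", ")))
  invisible(x)
}

#' Default drug-likeness filter set
#'
#' Lipinski-style property bounds (MW <= 500, logP <= 5, HBD <= 5,
#' HBA <= 10) plus a small deny-list of reactive groups (nitro, acyl
#' halide, peroxide).  These defaults are an editable starting point — the
#' framework, not the thresholds, is the contract — and ship as a YAML file
#' in `inst/extdata/default_filters.yaml`.
#'
#' @return A `filter_set`.
#' @export
default_filter_set <- function() {
  path <- system.file("extdata", "default_filters.yaml", package = "chemalign")
  filter_set(path)
}

# toolkit property table for the property-bound rules
filter_properties <- function(smiles) {
  sdf <- smiles_to_sdf(smiles, paste0("p", seq_along(smiles)))
  idx <- match(ChemmineR::sdfid(sdf), paste0("p", seq_along(smiles)))
  p <- ChemmineR::propOB(sdf)
  out <- data.frame(MW = rep(NA_real_, length(smiles)), logP = NA_real_,
                    TPSA = NA_real_, HBD = NA_real_, HBA = NA_real_,
                    MR = NA_real_)
  out[idx, ] <- data.frame(MW = p$MW, logP = p$logP, TPSA = p$TPSA,
                           HBD = p$HBD, HBA = p$HBA1, MR = p$MR)
  out
}

#' Apply a filter set to molecules
#'
#' @param molecules Character vector of canonical SMILES or tibble with
#'   `smiles`.
#' @param filterset A [filter_set()]; the empty set is the identity.
#' @return Tibble of retained molecules (`smiles`, input order preserved)
#'   with attribute `rejections`: a tibble of per-rule rejection counts.
#' @export
apply_filters <- function(molecules, filterset = default_filter_set()) {
  if (is.data.frame(molecules)) molecules <- molecules$smiles
  n <- length(molecules)
  rules <- filterset$rules
  if (length(rules) == 0 || n == 0) {
    out <- tibble(smiles = molecules)
    attr(out, "rejections") <- tibble(rule = character(0), n_rejected = integer(0))
    return(out)
  }
  needs_props <- any(vapply(rules, function(r) !is.null(r$property), logical(1)))
  props <- if (needs_props) filter_properties(molecules) else NULL
  needs_smarts <- any(vapply(rules, function(r) !is.null(r$pattern), logical(1)))
  obmols <- NULL
  if (needs_smarts) {
    sdf <- smiles_to_sdf(molecules, paste0("s", seq_len(n)))
    idx <- match(paste0("s", seq_len(n)), ChemmineR::sdfid(sdf))
    obmols <- lapply(idx, function(i) if (is.na(i)) NULL else ChemmineR::obmol(sdf[i]))
  }
  fail_rule <- rep(NA_character_, n)
  for (nm in names(rules)) {
    r <- rules[[nm]]
    open <- is.na(fail_rule)
    if (!any(open)) break
    if (!is.null(r$property)) {
      v <- props[[r$property]]
      bad <- open & (is.na(v) | v < (r$min %||% -Inf) | v > (r$max %||% Inf))
    } else {
      hit <- vapply(seq_len(n), function(i) {
        if (!open[i]) return(FALSE)
        if (is.null(obmols[[i]])) return(NA)
        ChemmineOB::smartsSearch_OB(obmols[[i]], r$pattern)[[1]] > 0
      }, logical(1))
      bad <- open & (is.na(hit) | (if (r$action == "deny") hit else !hit))
    }
    fail_rule[bad] <- nm
  }
  out <- tibble(smiles = molecules[is.na(fail_rule)])
  rej <- table(factor(fail_rule, levels = names(rules)))
  attr(out, "rejections") <- tibble(rule = names(rej),
                                    n_rejected = as.integer(rej))
  out
}
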