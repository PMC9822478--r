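# SMILES structure standardization.
#
# The preprocessing chain applied to every input structure before descriptor
# calculation, mirroring common QSAR practice: keep the largest
# carbon-containing fragment (salt stripping), remove stereochemistry, reject
# molecules with elements outside a configurable organic set, neutralize
# simple +1/-1 charges, and normalize heteroatom proton tautomers through a
# standard-InChI round trip. All chemistry is delegated to OpenBabel via
# ChemmineOB/ChemmineR.

#' Standardization settings
#'
#' @param organic_elements character vector of allowed element symbols. A
#'   molecule whose kept fragment contains any other element (or no carbon)
#'   is excluded as inorganic. Hydrogen is always allowed.
#' @param max_len maximum length, in characters, of the standardized SMILES;
#'   longer molecules are excluded (`too_long`). Stand-in for sequence-length
#'   limits of downstream SMILES-consuming models.
#' @param neutralize logical; neutralize simple +1/-1 charges where chemically
#'   possible (quaternary nitrogens stay charged and are kept).
#' @param tautomer_normalize logical; canonicalize heteroatom proton tautomers
#'   by round-tripping through standard InChI.
#' @return a list of class `std_config`.
#' @export
std_config <- function(organic_elements = c("H", "B", "C", "N", "O", "F",
                                            "P", "S", "Cl", "Br", "I"),
                       max_len = 200L,
                       neutralize = TRUE,
                       tautomer_normalize = TRUE) {
  stopifnot(is.character(organic_elements), max_len >= 1)
  structure(list(organic_elements = union("H", organic_elements),
                 max_len = as.integer(max_len),
                 neutralize = isTRUE(neutralize),
                 tautomer_normalize = isTRUE(tautomer_normalize)),
            class = "std_config")
}

# one OpenBabel SMILES -> canonical SMILES conversion; "" on parse failure
ob_convert <- function(smiles, from = "SMI", to = "CAN", op = NULL) {
  opts <- if (is.null(op)) {
    data.frame(names = character(0), args = character(0))
  } else {
    data.frame(names = op, args = "")
  }
  out <- tryCatch(
    ChemmineOB::convertFormat(from, to, smiles, options = opts),
    error = function(e) ""
  )
  # output is "<smiles>\t<title>\n"
  trimws(sub("\t.*", "", out))
}

# element symbols from a molecular formula string such as "C5H5NO" or "Na+"
formula_elements <- function(formula) {
  m <- gregexpr("[A-Z][a-z]?", formula)[[1]]
  if (m[1] == -1L) return(character(0))
  unique(substring(formula, m, m + attr(m, "match.length") - 1L))
}

# total atoms per element from a molecular formula such as "C5H5NO" or "Na+"
formula_counts <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)(\\d*)", formula)[[1]]
  if (m[1] == -1L) return(stats::setNames(integer(0), character(0)))
  tok <- substring(formula, m, m + attr(m, "match.length") - 1L)
  el <- sub("\\d+$", "", tok)
  n <- as.integer(sub("^[A-Za-z]+", "", tok))
  n[is.na(n)] <- 1L
  tapply(n, el, sum)
}

# per-fragment properties: canonical SMILES (with and without stereo),
# formula, heavy-atom count. prop_OB handles bond-less fragments (bare ions)
# that SDF-based property calculation rejects.
fragment_props <- function(frags) {
  rows <- lapply(frags, function(f) {
    pr <- tryCatch(ChemmineOB::forEachMol("SMILES", f, ChemmineOB::prop_OB)[[1L]],
                   error = function(e) NULL)
    if (is.null(pr) || !nzchar(trimws(pr$cansmi))) {
      return(data.frame(cansmi = "", cansmiNS = "", formula = "", heavy = 0,
                        stringsAsFactors = FALSE))
    }
    cnt <- formula_counts(pr$formula)
    data.frame(cansmi = trimws(pr$cansmi), cansmiNS = trimws(pr$cansmiNS),
               formula = pr$formula,
               heavy = sum(cnt[names(cnt) != "H"]), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Standardize one SMILES string
#'
#' Applies, in order: (1) largest-fragment selection (heavy-atom count, ties
#' broken by lexicographically smallest canonical SMILES) with removal of
#' stereochemistry; (2) organic-element filter; (3) neutralization of simple
#' charges; (4) tautomer normalization via standard InChI, emitting the
#' canonical SMILES. Deterministic: the same input always yields the same
#' output.
#'
#' @param smiles a single, non-empty SMILES string.
#' @param config a [std_config()].
#' @return a list with elements `smiles` (standardized SMILES, or `NA` when
#'   excluded) and `reason` (one of `"none"`, `"parse_failure"`,
#'   `"inorganic"`, `"empty_after_salt_strip"`, `"too_long"`).
#' @examples
#' \donttest{
#' standardize_smiles("[Na+].CC(=O)[O-]")  # -> CC(=O)O
#' }
#' @export
standardize_smiles <- function(smiles, config = std_config()) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(trimws(smiles)))
  stopifnot(inherits(config, "std_config"))
  excluded <- function(reason) list(smiles = NA_character_, reason = reason)

  full <- ob_convert(trimws(smiles))
  if (!nzchar(full)) return(excluded("parse_failure"))

  # salt strip: largest fragment of the canonical form
  frags <- strsplit(full, ".", fixed = TRUE)[[1]]
  frags <- frags[nzchar(frags)]
  if (length(frags) == 0L) return(excluded("empty_after_salt_strip"))
  props <- tryCatch(fragment_props(frags), error = function(e) NULL)
  if (is.null(props) || any(!nzchar(props$cansmi))) return(excluded("parse_failure"))
  best <- which(props$heavy == max(props$heavy))
  if (length(best) > 1L) best <- best[order(props$cansmi[best])[1L]]

  smi <- props$cansmiNS[best]  # canonical SMILES, stereo and isotopes removed
  if (!nzchar(smi)) return(excluded("empty_after_salt_strip"))

  elems <- formula_elements(props$formula[best])
  if (!("C" %in% elems) || length(setdiff(elems, config$organic_elements)) > 0L) {
    return(excluded("inorganic"))
  }

  if (config$neutralize) {
    out <- ob_convert(smi, op = "neutralize")
    if (nzchar(out)) smi <- out
  }

  if (config$tautomer_normalize) {
    inchi <- ob_convert(smi, to = "INCHI")
    if (nzchar(inchi)) {
      out <- ob_convert(inchi, from = "INCHI", to = "CAN")
      if (nzchar(out)) smi <- out
    }
  }

  if (!nzchar(smi)) return(excluded("empty_after_salt_strip"))
  if (nchar(smi) > config$max_len) return(excluded("too_long"))
  list(smiles = smi, reason = "none")
}

exclusion_reasons <- c("none", "parse_failure", "inorganic",
                       "empty_after_salt_strip", "too_long")

#' Standardize a dataset of molecules
#'
#' Batch wrapper around [standardize_smiles()]. Order-preserving; every input
#' record is either kept (with a standardized SMILES) or excluded with a
#' reason, and the exclusion report counts conserve the input size.
#'
#' @param data data.frame with columns `id`, `smiles`, `label` (0/1).
#' @param config a [std_config()].
#' @return an object of class `std_dataset`: list with `records` (data.frame
#'   `id`, `smiles_raw`, `smiles_std`, `label`, `excluded_reason`), `kept`
#'   (the kept subset), and `report` (named integer vector of counts per
#'   exclusion reason).
#' @export
standardize_dataset <- function(data, config = std_config()) {
  stopifnot(is.data.frame(data), all(c("id", "smiles", "label") %in% names(data)))
  ids <- as.character(data$id)
  if (anyDuplicated(ids)) {
    stop("duplicate ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  labels <- assert_binary_labels(data$label, "label")

  res <- lapply(as.character(data$smiles), function(s) {
    if (!nzchar(trimws(s))) return(list(smiles = NA_character_, reason = "parse_failure"))
    standardize_smiles(s, config)
  })
  records <- data.frame(
    id = ids,
    smiles_raw = as.character(data$smiles),
    smiles_std = vapply(res, `[[`, character(1), "smiles"),
    label = labels,
    excluded_reason = vapply(res, `[[`, character(1), "reason"),
    stringsAsFactors = FALSE
  )
  report <- table(factor(records$excluded_reason, levels = exclusion_reasons))
  report <- stats::setNames(as.integer(report), exclusion_reasons)
  structure(list(records = records,
                 kept = records[records$excluded_reason == "none", , drop = FALSE],
                 report = report),
            class = "std_dataset")
}

#' @export
print.std_dataset <- function(x, ...) {
  cat("Standardized dataset:", nrow(x$records), "molecules,",
      nrow(x$kept), "kept\n")
  excl <- x$report[x$report > 0 & names(x$report) != "none"]
  if (length(excl)) {
    cat("Exclusions:\n")
    for (r in names(excl)) cat(sprintf("  %-24s %d\n", r, excl[[r]]))
  }
  invisible(x)
}
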