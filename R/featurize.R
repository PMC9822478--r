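# Physico-chemical descriptor calculation and external feature ingestion.
#
# Descriptors are computed with the OpenBabel/ChemmineR toolchain. The default
# descriptor list ships as data (inst/extdata/descriptors.yaml): swapping the
# list never requires a code change. External, precomputed feature files
# (e.g. learned embeddings) enter through load_external_features().

# descriptor registry ---------------------------------------------------------

.ob_numeric_props <- c("MW", "logP", "TPSA", "MR", "HBA1", "HBA2", "HBD", "nF")
.group_names <- c("RNH2", "R2NH", "R3N", "ROPO3", "ROH", "RCHO", "RCOR",
                  "RCOOH", "RCOOR", "ROR", "RCCH", "RCN")
.count_elements <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I")

#' Names of all descriptors the package can compute
#' @return character vector of valid descriptor names.
#' @export
available_descriptors <- function() {
  c(.ob_numeric_props, "natoms", "nrings", "naromrings",
    paste0("n", .count_elements), .group_names)
}

#' Default descriptor list
#'
#' Reads the descriptor list shipped with the package (a YAML file listing
#' descriptor names). The list is configuration, not code: point `file` at
#' your own YAML to change the feature set.
#'
#' @param file path to a YAML file containing a list of descriptor names.
#' @return character vector of descriptor names.
#' @export
default_descriptors <- function(file = system.file("extdata", "descriptors.yaml",
                                                   package = "macp")) {
  unlist(yaml::read_yaml(file))
}

#' Compute the descriptor matrix for standardized molecules
#'
#' One row per molecule, one column per descriptor, computed with OpenBabel /
#' ChemmineR. Deterministic. Molecules for which any requested descriptor is
#' missing or non-finite are dropped with a warning (never imputed, to keep
#' calibration exchangeability intact); their ids are recorded in the
#' `"dropped"` attribute of the result.
#'
#' @param data data.frame of standardized molecules with columns `id` and
#'   `smiles_std` (or `smiles`), e.g. the `kept` component of
#'   [standardize_dataset()].
#' @param descriptors character vector of descriptor names; see
#'   [available_descriptors()]. Unknown names are an error.
#' @return numeric matrix with rownames = ids and colnames = descriptors, all
#'   entries finite.
#' @export
compute_descriptors <- function(data, descriptors = default_descriptors()) {
  stopifnot(is.data.frame(data), "id" %in% names(data))
  smi_col <- if ("smiles_std" %in% names(data)) "smiles_std" else "smiles"
  stopifnot(smi_col %in% names(data))
  unknown <- setdiff(descriptors, available_descriptors())
  if (length(unknown) > 0L) {
    stop("unknown descriptor name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  ids <- as.character(data$id)
  if (anyDuplicated(ids)) stop("duplicate ids", call. = FALSE)
  if (nrow(data) == 0L) {
    return(matrix(numeric(0), 0L, length(descriptors),
                  dimnames = list(character(0), descriptors)))
  }

  sdf <- ChemmineR::smiles2sdf(stats::setNames(as.character(data[[smi_col]]), ids))
  pr <- ChemmineR::propOB(sdf)
  counts <- ChemmineR::atomcount(sdf)
  # rings()/groups() drop to a vector for a single molecule
  ring <- ChemmineR::rings(sdf, type = "count", arom = TRUE)
  if (is.null(dim(ring))) ring <- matrix(ring, 1L, dimnames = list(ids[1L], names(ring)))
  grp <- ChemmineR::groups(sdf, groups = "fctgroup", type = "countMA")
  if (is.null(dim(grp))) grp <- matrix(grp, 1L, dimnames = list(ids[1L], names(grp)))

  full <- matrix(NA_real_, nrow(data), length(available_descriptors()),
                 dimnames = list(ids, available_descriptors()))
  for (d in .ob_numeric_props) full[, d] <- as.numeric(pr[[d]])
  full[, "natoms"] <- vapply(counts, function(v) sum(v[names(v) != "H"]), numeric(1))
  full[, "nrings"] <- as.numeric(ring[, "RINGS"])
  full[, "naromrings"] <- as.numeric(ring[, "AROMATIC"])
  for (el in .count_elements) {
    full[, paste0("n", el)] <-
      vapply(counts, function(v) sum(v[names(v) == el]), numeric(1))
  }
  grp <- as.matrix(grp)
  for (g in .group_names) {
    full[, g] <- if (g %in% colnames(grp)) as.numeric(grp[, g]) else 0
  }

  out <- full[, descriptors, drop = FALSE]
  bad <- !apply(out, 1L, function(r) all(is.finite(r)))
  if (any(bad)) {
    warning("dropped ", sum(bad), " molecule(s) with failed descriptors: ",
            paste(utils::head(ids[bad], 10L), collapse = ", "), call. = FALSE)
  }
  res <- out[!bad, , drop = FALSE]
  if (any(bad)) attr(res, "dropped") <- ids[bad]
  res
}

#' Load a precomputed feature file
#'
#' Entry point for externally generated feature vectors (learned embeddings,
#' descriptors computed elsewhere): a CSV whose first column is the molecule
#' id and whose remaining columns are numeric.
#'
#' @param path CSV path; header required; first column is `id`.
#' @param expected_ids character vector; the returned matrix has exactly these
#'   rows, in this order. Any id absent from the file is a hard error.
#' @return numeric matrix (rows = `expected_ids`, columns = feature names).
#' @export
load_external_features <- function(path, expected_ids) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("feature file needs an id column plus numeric columns",
                          call. = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate ids in feature file", call. = FALSE)
  expected_ids <- as.character(expected_ids)
  missing <- setdiff(expected_ids, ids)
  if (length(missing) > 0L) {
    stop("feature file is missing id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1L]
      stop(sprintf("non-numeric value in feature file at row %d, column '%s'",
                   bad, names(vals)[j]), call. = FALSE)
    }
    if (anyNA(v) || any(!is.finite(v))) {
      bad <- which(!is.finite(v))[1L]
      stop(sprintf("missing/non-finite value in feature file at row %d, column '%s'",
                   bad, names(vals)[j]), call. = FALSE)
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  m[expected_ids, , drop = FALSE]
}
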