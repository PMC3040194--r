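# Trait-table validation and dummy-coded design matrices.

#' Validate a species trait table
#'
#' The trait table is tabular data with one row per species:
#' `species` (unique identifier), `hct` (hematocrit as percent packed cell
#' volume, strictly inside (0, 100)), `habitat` and `clade` (labels from the
#' closed vocabularies of [trait_levels()]).
#'
#' The (0, 100) range is enforced at the I/O boundary
#' ([read_trait_table()]): measured hematocrit is a percentage. Internally
#' (fitting, simulation) only finiteness is required, because the Gaussian
#' generative model can legitimately produce simulated values outside the
#' biological range under extreme configurations.
#'
#' @param traits A data frame with columns `species`, `hct`, `habitat`,
#'   `clade`.
#' @param strict_range Enforce `hct` strictly inside (0, 100)?
#' @return The validated table as a tibble.
#' @export
validate_traits <- function(traits, strict_range = FALSE) {
  need <- c("species", "hct", "habitat", "clade")
  miss <- setdiff(need, names(traits))
  if (length(miss)) {
    abort(sprintf("Trait table is missing columns: %s", paste(miss, collapse = ", ")))
  }
  traits <- tibble::as_tibble(traits)
  dup <- unique(traits$species[duplicated(traits$species)])
  if (length(dup)) abort(sprintf("Duplicate species in trait table: %s", paste(dup, collapse = ", ")))
  if (!is.numeric(traits$hct) || any(!is.finite(traits$hct))) {
    abort("`hct` must be finite numeric (percent packed cell volume).")
  }
  if (strict_range && any(traits$hct <= 0 | traits$hct >= 100)) {
    bad <- traits$species[traits$hct <= 0 | traits$hct >= 100]
    abort(sprintf("`hct` outside (0, 100) for: %s", paste(bad, collapse = ", ")))
  }
  for (fac in c("habitat", "clade")) {
    vocab <- trait_levels()[[fac]]
    bad <- !traits[[fac]] %in% vocab
    if (any(bad)) {
      abort(sprintf(
        "Unknown %s level(s) %s (rows: %s). Allowed: %s",
        fac,
        paste(unique(traits[[fac]][bad]), collapse = ", "),
        paste(which(bad), collapse = ", "),
        paste(vocab, collapse = ", ")
      ))
    }
  }
  traits
}

#' Read a trait table from CSV/TSV
#'
#' Expects header columns `species`, `hct`, `habitat`, `clade` (extra
#' columns are kept). The delimiter is inferred from the extension
#' (`.tsv`/`.tab` means tab, otherwise comma).
#'
#' @param path File path.
#' @return A validated trait tibble.
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("Trait file not found: %s", path))
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE)
  df <- validate_traits(df)
  if (any(df$hct <= 0 | df$hct >= 100)) {
    warn(sprintf("hct outside (0, 100) for: %s",
                 paste(df$species[df$hct <= 0 | df$hct >= 100], collapse = ", ")))
  }
  df
}

#' Write a trait table to CSV
#'
#' @param traits A trait table.
#' @param path Output path.
#' @return The table, invisibly.
#' @export
write_trait_table <- function(traits, path) {
  traits <- validate_traits(traits)
  utils::write.csv(traits, path, row.names = FALSE, quote = FALSE)
  invisible(traits)
}

#' Build a dummy-coded design matrix
#'
#' Parallel-slopes ANCOVA coding: an intercept column of ones plus 0/1 dummy
#' columns for every non-base factor level present in the data. Base levels
#' are `Terrestrial` (habitat) and `Colubrinae` (clade); column order is
#' intercept, then habitat dummies, then clade dummies, in the canonical
#' order of [trait_levels()]. With all levels present the full model has
#' p = 10 columns.
#'
#' @param traits A trait table.
#' @param factors Character subset of `c("habitat", "clade")`; empty means
#'   intercept-only.
#' @return A numeric n x p matrix with column names; attributes `factors`
#'   (named list mapping each factor to its dummy column names) and
#'   `base_levels`.
#' @export
#' @examples
#' tr <- tibble::tibble(
#'   species = c("a", "b"), hct = c(25, 30),
#'   habitat = c("Terrestrial", "Marine"), clade = c("Colubrinae", "Elapidae")
#' )
#' build_design(tr, c("habitat", "clade"))
build_design <- function(traits, factors = c("habitat", "clade")) {
  traits <- validate_traits(traits)
  if (!all(factors %in% c("habitat", "clade"))) {
    abort("`factors` must be a subset of c(\"habitat\", \"clade\").")
  }
  n <- nrow(traits)
  X <- matrix(1, n, 1, dimnames = list(traits$species, "(Intercept)"))
  col_map <- list()
  for (fac in c("habitat", "clade")) {     # fixed order: habitat block first
    if (!fac %in% factors) next
    vocab <- trait_levels()[[fac]]
    base <- vocab[1]
    if (!base %in% traits[[fac]]) {
      abort(sprintf("Base %s level '%s' absent from the data; dummy coding undefined.", fac, base))
    }
    present <- vocab[-1][vocab[-1] %in% traits[[fac]]]
    if (length(present)) {
      dummies <- sapply(present, function(lv) as.numeric(traits[[fac]] == lv))
      dummies <- matrix(dummies, nrow = n, dimnames = list(traits$species, present))
      X <- cbind(X, dummies)
      col_map[[fac]] <- present
    } else {
      col_map[[fac]] <- character(0)
    }
  }
  attr(X, "factors") <- col_map
  attr(X, "base_levels") <- c(habitat = "Terrestrial", clade = "Colubrinae")
  X
}
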