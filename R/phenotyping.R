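# Boolean marker-combination phenotyping: each TIIC population is a named
# rule of required-positive and required-negative markers; a cell carries
# every rule it satisfies (parent lineages alongside full sub-types).

#' Define a phenotype rule
#'
#' A phenotype rule names a TIIC population by its boolean marker signature:
#' all `positive` markers positive and all `negative` markers negative. The
#' first positive marker is the lineage marker by convention. The canonical
#' name is generated from the signature (`"CD8+PD-1+LAG-3-"`); an `alias`
#' (e.g. `"M1"`) may be attached.
#'
#' @param positive character vector of required-positive markers (first =
#'   lineage marker).
#' @param negative character vector of required-negative markers.
#' @param name optional canonical name override.
#' @param alias optional short alias.
#' @return An object of class `phenotype_rule`.
#' @export
#' @examples
#' phenotype_rule(c("CD8", "PD-1"), "LAG-3")$name
phenotype_rule <- function(positive, negative = character(), name = NULL,
                           alias = NULL) {
  stopifnot(is.character(positive), length(positive) >= 1)
  negative <- as.character(negative)
  if (length(intersect(positive, negative)))
    stop("marker(s) listed both positive and negative: ",
         paste(intersect(positive, negative), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(c(positive, negative)))
    stop("duplicated marker in rule", call. = FALSE)
  if (is.null(name))
    name <- paste0(paste0(positive, "+", collapse = ""),
                   if (length(negative))
                     paste0(negative, "-", collapse = "") else "")
  structure(list(name = name, lineage_marker = positive[1],
                 positive = positive, negative = negative, alias = alias),
            class = "phenotype_rule")
}

#' @export
print.phenotype_rule <- function(x, ...) {
  cat("<phenotype_rule>", x$name,
      if (!is.null(x$alias)) paste0("(", x$alias, ")"), "\n")
  invisible(x)
}

#' Build a phenotype registry
#'
#' A registry is a named collection of [phenotype_rule()]s, validated for
#' unique names. Rules referencing markers absent from a panel are rejected
#' at registry validation time, not per cell.
#'
#' @param rules list of `phenotype_rule` objects.
#' @param panel optional panel configuration to validate marker names
#'   against.
#' @return A named list of rules, class `phenotype_registry`.
#' @export
phenotype_registry <- function(rules, panel = NULL) {
  stopifnot(is.list(rules),
            all(vapply(rules, inherits, TRUE, "phenotype_rule")))
  names(rules) <- vapply(rules, `[[`, "", "name")
  if (anyDuplicated(names(rules)))
    stop("duplicate rule names in registry", call. = FALSE)
  reg <- structure(rules, class = "phenotype_registry")
  if (!is.null(panel)) validate_registry(reg, panel)
  reg
}

#' @export
`[.phenotype_registry` <- function(x, i) {
  r <- unclass(x)[i]
  if (any(vapply(r, is.null, TRUE)))
    stop("phenotype(s) absent from registry: ",
         paste(setdiff(as.character(i), names(x)), collapse = ", "),
         call. = FALSE)
  structure(r, class = "phenotype_registry")
}

#' Validate a registry against a marker panel
#' @param registry a `phenotype_registry`.
#' @param panel a `tiic_panel` from [default_panel()].
#' @return `registry`, invisibly; errors if any rule references an unknown
#'   marker.
#' @export
validate_registry <- function(registry, panel = default_panel()) {
  stopifnot(inherits(registry, "phenotype_registry"))
  for (r in registry) {
    unknown <- setdiff(c(r$positive, r$negative), panel$markers)
    if (length(unknown))
      stop("rule '", r$name, "' references marker(s) not in panel '",
           panel$name, "': ", paste(unknown, collapse = ", "),
           call. = FALSE)
  }
  invisible(registry)
}

#' Default TIIC population registry
#'
#' The main lineage and sub-population rules of the gastric-cancer m-IHC
#' design this package implements: CD8 T-cell checkpoint combinations
#' (PD-1/LAG-3/TIM-3), CD4 regulatory combinations (FoxP3/CTLA-4/PD-L1),
#' macrophage polarisation and STING states (CD68/CD163/HLA-DR/STING), B
#' cells (CD20) and neutrophils (CD66b). Macrophage polarity aliases follow
#' the source study's usage: M1 = CD68+CD163+HLA-DR-, M2 = CD68+HLA-DR+CD163-
#' (note this inverts the common convention; the canonical marker-string
#' names are primary). The four signature populations are always present.
#' User-defined rules can be merged via [phenotype_registry()] or loaded
#' from YAML via [registry_from_yaml()].
#'
#' @return A `phenotype_registry`.
#' @export
default_registry <- function() {
  r <- list(
    # lineages
    phenotype_rule("CD8"), phenotype_rule("CD4"), phenotype_rule("CD68"),
    phenotype_rule("CD20"), phenotype_rule("CD66b"),
    # CD8 checkpoint sub-populations
    phenotype_rule(c("CD8", "PD-1", "LAG-3", "TIM-3")),
    phenotype_rule(c("CD8", "PD-1", "LAG-3"), "TIM-3"),
    phenotype_rule(c("CD8", "PD-1", "TIM-3"), "LAG-3"),
    phenotype_rule(c("CD8", "PD-1"), c("LAG-3", "TIM-3")),
    phenotype_rule(c("CD8", "PD-1", "TIM-3")),
    phenotype_rule(c("CD8", "PD-1", "LAG-3")),
    phenotype_rule(c("CD8", "PD-1"), "LAG-3"),
    phenotype_rule(c("CD8", "TIM-3"), "PD-1"),
    phenotype_rule("CD8", c("PD-1", "LAG-3")),
    phenotype_rule("CD8", c("PD-1", "LAG-3", "TIM-3")),
    # CD4 sub-populations
    phenotype_rule(c("CD4", "FoxP3")),
    phenotype_rule("CD4", "FoxP3"),
    phenotype_rule(c("CD4", "FoxP3", "CTLA-4")),
    phenotype_rule(c("CD4", "CTLA-4"), "FoxP3"),
    phenotype_rule(c("CD4", "FoxP3", "PD-L1")),
    phenotype_rule(c("CD4", "PD-L1"), "FoxP3"),
    # macrophages
    phenotype_rule(c("CD68", "STING")),
    phenotype_rule(c("CD68", "CD163"), "HLA-DR", alias = "M1"),
    phenotype_rule(c("CD68", "HLA-DR"), "CD163", alias = "M2"),
    phenotype_rule(c("CD68", "HLA-DR", "STING"), "CD163")
  )
  phenotype_registry(r)
}

#' Enumerate a full-sign rule family
#'
#' All `2^k` sign assignments of `markers` on top of a positive lineage
#' marker, e.g. the 8 CD8 checkpoint combinations over PD-1/LAG-3/TIM-3.
#' Families built this way are mutually exclusive and jointly exhaustive
#' over lineage-positive cells.
#'
#' @param lineage lineage marker (always positive).
#' @param markers markers to assign both signs over.
#' @return A `phenotype_registry` of `2^length(markers)` rules.
#' @export
full_sign_family <- function(lineage, markers) {
  stopifnot(length(markers) >= 1)
  signs <- expand.grid(rep(list(c(TRUE, FALSE)), length(markers)))
  rules <- lapply(seq_len(nrow(signs)), function(i) {
    pos <- markers[unlist(signs[i, ])]
    neg <- markers[!unlist(signs[i, ])]
    phenotype_rule(c(lineage, pos), neg)
  })
  phenotype_registry(rules)
}

#' Assign phenotypes to cells
#'
#' Applies every rule in the registry to every cell: a cell matches a rule
#' iff all the rule's positive markers are positive and all its negative
#' markers negative on that cell. Tumour-flagged cells never match an
#' immune phenotype. Assignment is independent of cell order.
#'
#' @param cells cell data.frame (from a `tiic_cell_data`) with one logical
#'   column per marker and an `is_tumour_cell` column.
#' @param registry a `phenotype_registry`.
#' @return Logical matrix, cells x rules, with rule names as columns.
#' @export
assign_phenotypes <- function(cells, registry) {
  stopifnot(inherits(registry, "phenotype_registry"))
  need <- unique(unlist(lapply(registry, function(r) c(r$positive,
                                                       r$negative))))
  miss <- setdiff(need, names(cells))
  if (length(miss))
    stop("cells lack marker column(s) referenced by registry: ",
         paste(miss, collapse = ", "), call. = FALSE)
  n <- nrow(cells)
  out <- matrix(FALSE, n, length(registry),
                dimnames = list(cells$cell_id, names(registry)))
  immune <- !cells$is_tumour_cell
  for (j in seq_along(registry)) {
    r <- registry[[j]]
    m <- immune
    for (mk in r$positive) m <- m & cells[[mk]]
    for (mk in r$negative) m <- m & !cells[[mk]]
    out[, j] <- m
  }
  out
}

#' Phenotype names of a single cell
#' @param cell one-row cell data.frame.
#' @inheritParams assign_phenotypes
#' @return Character vector of matching rule names.
#' @export
cell_phenotypes <- function(cell, registry) {
  hits <- assign_phenotypes(cell, registry)
  colnames(hits)[hits[1, ]]
}

#' Serialise / load a registry as YAML
#'
#' Each entry carries `name`, `positive`, `negative` and optional `alias`.
#'
#' @param registry a `phenotype_registry`.
#' @param path YAML file.
#' @return `registry_to_yaml()`: `path` invisibly; `registry_from_yaml()`:
#'   a `phenotype_registry`.
#' @export
registry_to_yaml <- function(registry, path) {
  entries <- lapply(unname(registry), function(r) {
    e <- list(name = r$name, positive = as.list(r$positive),
              negative = as.list(r$negative))
    if (!is.null(r$alias)) e$alias <- r$alias
    e
  })
  yaml::write_yaml(entries, path)
  invisible(path)
}

#' @rdname registry_to_yaml
#' @export
registry_from_yaml <- function(path) {
  entries <- yaml::read_yaml(path)
  rules <- lapply(entries, function(e) {
    phenotype_rule(unlist(e$positive), unlist(e$negative),
                   name = e$name, alias = e$alias)
  })
  phenotype_registry(rules)
}
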