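specificity_caveat <- paste(
  "Note: clade specificity is relative to the sampled outgroup;",
  "subfamilies called specific here may still occur in unsampled species.")

#' Call clade-specific subfamilies against a declared ingroup
#'
#' A subfamily is clade-specific when its species multiset is contained in
#' the ingroup (no outgroup member) and it spans at least
#' `min_ingroup_species` ingroup species (default 1: a subfamily private to
#' a single ingroup species still counts, matching the set-inclusion
#' definition).
#'
#' @param assignment a [subfamily_assignment()] with species filled in.
#' @param ingroup character vector of ingroup species.
#' @param species_universe optional vector of all valid species; member
#'   species outside it raise an error.
#' @param min_ingroup_species minimum distinct ingroup species required.
#' @return data.frame of class `specificity_calls` with columns
#'   subfamily_id, specific, ingroup_species_present,
#'   outgroup_species_present; carries a `caveat` attribute surfacing that
#'   specificity is relative to the sampled outgroup.
#' @export
call_clade_specific <- function(assignment, ingroup, species_universe = NULL,
                                min_ingroup_species = 1) {
  if (length(ingroup) == 0) stop("ingroup must be non-empty")
  genes <- assignment$genes
  if (nrow(genes) == 0) {
    out <- data.frame(subfamily_id = character(0), specific = logical(0),
                      ingroup_species_present = integer(0),
                      outgroup_species_present = integer(0))
    return(structure(out, class = c("specificity_calls", "data.frame"),
                     caveat = specificity_caveat))
  }
  if (anyNA(genes$species)) stop("assignment is missing species labels")
  if (!is.null(species_universe)) {
    unknown <- setdiff(unique(genes$species), species_universe)
    if (length(unknown) > 0) {
      stop("member species outside the declared species universe: ",
           paste(unknown, collapse = ", "))
    }
  }
  sfs <- unique(genes$subfamily_id)
  rows <- lapply(sfs, function(sf) {
    sp <- genes$species[genes$subfamily_id == sf]
    n_in <- length(unique(sp[sp %in% ingroup]))
    n_out <- length(unique(sp[!sp %in% ingroup]))
    data.frame(subfamily_id = sf,
               specific = n_out == 0 && n_in >= min_ingroup_species,
               ingroup_species_present = n_in,
               outgroup_species_present = n_out, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("specificity_calls", "data.frame"),
            caveat = specificity_caveat)
}

#' Class-count summary for a focal species
#'
#' Counts, restricted to the focal species: genes and subfamilies in
#' clade-specific vs shared classes. The conservation invariants (gene
#' counts sum to the focal species' superfamily size; subfamily counts sum
#' to the number of subfamilies containing the focal species) are asserted.
#'
#' @param calls output of [call_clade_specific()].
#' @param assignment the matching [subfamily_assignment()].
#' @param focal_species species label present in at least one subfamily.
#' @return object of class `specificity_summary`: list with
#'   n_specific_subfamilies, n_shared_subfamilies, n_specific_genes_focal,
#'   n_shared_genes_focal, focal_total_genes, focal_species, report_text.
#' @export
specificity_summary <- function(calls, assignment, focal_species) {
  genes <- assignment$genes
  if (!focal_species %in% genes$species) {
    stop("unknown focal species: ", focal_species)
  }
  specific_sfs <- calls$subfamily_id[calls$specific]
  focal <- genes[genes$species == focal_species, ]
  sf_focal <- unique(focal$subfamily_id)
  n_spec_sf <- sum(sf_focal %in% specific_sfs)
  n_shared_sf <- length(sf_focal) - n_spec_sf
  n_spec_genes <- sum(focal$subfamily_id %in% specific_sfs)
  n_shared_genes <- nrow(focal) - n_spec_genes
  stopifnot(n_spec_genes + n_shared_genes == nrow(focal),
            n_spec_sf + n_shared_sf == length(sf_focal))
  structure(list(n_specific_subfamilies = n_spec_sf,
                 n_shared_subfamilies = n_shared_sf,
                 n_specific_genes_focal = n_spec_genes,
                 n_shared_genes_focal = n_shared_genes,
                 focal_total_genes = nrow(focal),
                 focal_species = focal_species,
                 report_text = paste0(
                   focal_species, ": ", nrow(focal), " superfamily genes in ",
                   length(sf_focal), " subfamilies; ", n_spec_sf,
                   " clade-specific subfamilies (", n_spec_genes, " genes), ",
                   n_shared_sf, " shared subfamilies (", n_shared_genes,
                   " genes). ", specificity_caveat)),
            class = "specificity_summary")
}

#' @export
print.specificity_summary <- function(x, ...) {
  cat(x$report_text, "\n")
  invisible(x)
}
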