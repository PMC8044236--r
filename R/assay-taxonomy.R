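#' The assay taxonomy: which endpoint group each assay type feeds
#'
#' The three weight-of-evidence endpoint groups follow the ICH S2(R1) test
#' batteries. Y1 is the bacterial reverse mutation (Ames) test. Y2 holds the
#' in vivo mammalian cytogenetic assays (erythrocyte micronucleus, bone
#' marrow chromosome aberration), which substitute for one another. Y3 pools
#' the third slot of both standard combinations (in vitro chromosomal
#' aberration, in vitro TK gene mutation, spermatocyte chromosome
#' aberration, rodent dominant lethal) together with the supplementary
#' assays used when those are missing (HGPRT gene mutation, unscheduled DNA
#' synthesis, Drosophila sex-linked recessive lethal).
#'
#' @param extra optional named character vector extending the taxonomy;
#'   names are new assay codes, values their endpoint group (`"Y1"`,
#'   `"Y2"`, `"Y3"`, or `"unused"`). Existing codes cannot be remapped.
#' @return named character vector mapping assay code to endpoint group.
#' @examples
#' assay_taxonomy()["AMES"]
#' classify_assay(c("AMES", "MN_VIVO", "HGPRT"))
#' @export
assay_taxonomy <- function(extra = NULL) {
  tax <- c(
    AMES       = "Y1",
    MN_VIVO    = "Y2",
    BM_CA      = "Y2",
    VITRO_CA   = "Y3",
    TK         = "Y3",
    SPERM_CA   = "Y3",
    DOM_LETHAL = "Y3",
    HGPRT      = "Y3",
    UDS        = "Y3",
    SLRL       = "Y3"
  )
  if (!is.null(extra)) {
    if (is.null(names(extra)) || any(names(extra) == "") ||
        anyDuplicated(names(extra))) {
      stop_mutafuse("'extra' must be a uniquely named character vector",
                    "mutafuse_taxonomy_error")
    }
    if (any(names(extra) %in% names(tax))) {
      stop_mutafuse("cannot remap built-in assay codes", "mutafuse_taxonomy_error")
    }
    bad <- !extra %in% c("Y1", "Y2", "Y3", "unused")
    if (any(bad)) {
      stop_mutafuse(
        sprintf("invalid endpoint group(s): %s",
                paste(unique(extra[bad]), collapse = ", ")),
        "mutafuse_taxonomy_error")
    }
    tax <- c(tax, extra)
  }
  tax
}

#' Map assay codes to their weight-of-evidence endpoint group
#'
#' @param assay_code character vector of assay codes
#' @param taxonomy taxonomy mapping, see [assay_taxonomy()]
#' @return character vector of endpoint groups (`"Y1"`/`"Y2"`/`"Y3"`)
#' @export
classify_assay <- function(assay_code, taxonomy = assay_taxonomy()) {
  unknown <- setdiff(unique(assay_code), names(taxonomy))
  if (length(unknown) > 0) {
    stop_mutafuse(
      sprintf("unknown assay code(s): %s", paste(unknown, collapse = ", ")),
      "mutafuse_taxonomy_error")
  }
  unname(taxonomy[assay_code])
}
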