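# Internal-standard quantification: class-matched standard assignment,
# area-ratio concentration, and LSI quantification levels.

#' Default internal-standard set
#'
#' One deuterated surrogate per head class Cer/HexCer/Hex2Cer plus C18:0
#' GM3-d5, each spiked at 10 nM in the extraction solvent. The exact
#' composition is configurable; classes without a dedicated standard fall
#' back by the nearest-class rule of [assign_internal_standard()].
#'
#' @param spiked_conc Spiked concentration in nM (default 10).
#' @return Data frame: `name` (deuterated species name), `head_class`,
#'   `spiked_conc`.
#' @export
default_internal_standards <- function(spiked_conc = 10) {
  data.frame(
    name = c("Cer 18:1;O2/12:0(d7)", "HexCer 18:1;O2/12:0(d7)",
             "Hex2Cer 18:1;O2/12:0(d7)", "GM3 18:1;O2/18:0(d5)"),
    head_class = c("Cer", "HexCer", "Hex2Cer", "GM3"),
    spiked_conc = spiked_conc,
    stringsAsFactors = FALSE
  )
}

# similarity order along the glycosylation chain; GM3 re-enters at Hex2Cer
.class_position <- c(Cer = 0, HexCer = 1, Hex2Cer = 2, Hex3Cer = 3,
                     HexNAcHex3Cer = 4, GM3 = 2)

#' Assign the internal standard for a species
#'
#' Exact head-class match when available; otherwise the nearest class under
#' the fixed similarity order Cer - HexCer - Hex2Cer - Hex3Cer -
#' HexNAcHex3Cer, with GM3 falling back to Hex2Cer. Ties break toward the
#' less glycosylated class, so the choice is deterministic.
#'
#' @param species A `sphingolipid_species`, parseable name, or head-class
#'   label.
#' @param standards Data frame of standards (see
#'   [default_internal_standards()]).
#' @return The matching row of `standards` (one-row data frame).
#' @export
assign_internal_standard <- function(species, standards = default_internal_standards()) {
  if (is.null(standards) || nrow(standards) == 0L)
    stop("internal-standard list is empty")
  cls <- if (is.character(species) && species %in% names(.class_position)) species
         else {
           if (is.character(species)) species <- parse_species_name(species)
           species$head_class
         }
  hit <- which(standards$head_class == cls)
  if (!length(hit)) {
    pos <- .class_position[[cls]]
    spos <- .class_position[standards$head_class]
    d <- abs(spos - pos)
    hit <- which(d == min(d))
    if (length(hit) > 1L) hit <- hit[which.min(spos[hit])]
  }
  standards[hit[1L], , drop = FALSE]
}

#' Concentration from the internal-standard area ratio
#'
#' `conc = analyte_area / is_area * is_conc * volume_factor`. The default
#' volume factor of 10 reflects 20 ul plasma extracted into 200 ul solvent.
#' Non-positive standard areas yield a missing value with a warning rather
#' than an error: a lost standard invalidates only its dependent species.
#'
#' @param analyte_area,is_area Peak areas (vectorised).
#' @param is_conc Standard concentration in the extract, nM (default 10).
#' @param volume_factor Plasma-to-extract dilution factor (default 10).
#' @return Plasma concentration in nM.
#' @export
concentration <- function(analyte_area, is_area, is_conc = 10, volume_factor = 10) {
  stopifnot(is_conc > 0, volume_factor > 0)
  bad <- !is.finite(is_area) | is_area <= 0
  if (any(bad)) {
    warning(sum(bad), " injection(s) with missing or non-positive internal-standard",
            " signal; dependent concentrations set to NA")
    is_area[bad] <- NA_real_
  }
  analyte_area / is_area * is_conc * volume_factor
}

#' LSI quantification level for a species
#'
#' Level 2 (class-matched internal standard) for Cer, DHS-Cer, HexCer,
#' Hex2Cer and GM3; level 3 (surrogate standard) for Hex3Cer and all other
#' classes.
#'
#' @param species A panel data frame (vectorised over rows), a
#'   `sphingolipid_species`, or a parseable name.
#' @return Integer level(s), 2 or 3.
#' @export
assign_quant_level <- function(species) {
  sub <- if (is.data.frame(species)) species$subclass
         else {
           if (is.character(species)) species <- parse_species_name(species)
           species$subclass
         }
  ifelse(sub %in% c("Cer", "DHS-Cer", "HexCer", "Hex2Cer", "GM3"), 2L, 3L)
}

#' Quantify an annotated injection run
#'
#' Converts annotated peak areas to plasma concentrations per injection using
#' each species' assigned internal standard, then assembles the
#' concentration table for study samples.
#'
#' @param annotated Annotated peaks (from [match_peaks()]): columns
#'   `injection_id`, `name`, `area`; internal-standard species must be
#'   present among the annotations.
#' @param manifest Injection-sequence manifest: `injection_id`, `role`,
#'   `batch`, `order`, `sample_id` (study injections), `dilution_factor`.
#' @param panel Panel data frame (defines the species columns and classes).
#' @param standards Internal-standard table.
#' @param volume_factor Plasma-to-extract factor (default 10).
#' @param roles Injection roles to quantify (default `"study"`).
#' @return Data frame: `sample_id` then one column per panel species
#'   (plasma nM). Attribute `quant_level` carries the per-species level.
#' @export
quantify_run <- function(annotated, manifest, panel,
                         standards = default_internal_standards(),
                         volume_factor = 10, roles = "study") {
  keep <- manifest[manifest$role %in% roles, , drop = FALSE]
  keep <- keep[order(keep$order), , drop = FALSE]
  inj <- keep$injection_id

  areas <- area_matrix(annotated, c(panel$name, standards$name), inj)
  is_for <- vapply(seq_len(nrow(panel)), function(i)
    assign_internal_standard(panel$head_class[i], standards)$name, "")
  is_conc <- standards$spiked_conc[match(is_for, standards$name)]

  conc <- matrix(NA_real_, nrow = length(inj), ncol = nrow(panel),
                 dimnames = list(inj, panel$name))
  for (i in seq_len(nrow(panel))) {
    conc[, i] <- suppressWarnings(
      concentration(areas[, panel$name[i]], areas[, is_for[i]],
                    is_conc[i], volume_factor))
  }
  n_bad <- sum(!is.finite(areas[, unique(is_for), drop = FALSE]) |
                 areas[, unique(is_for), drop = FALSE] <= 0)
  if (n_bad > 0)
    warning("missing internal-standard signal in ", n_bad,
            " injection x standard cell(s); dependent species set to NA")

  out <- data.frame(sample_id = if ("sample_id" %in% names(keep)) keep$sample_id else inj,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(conc, check.names = FALSE))
  rownames(out) <- NULL
  structure(out, quant_level = stats::setNames(assign_quant_level(panel), panel$name))
}

#' Long annotated peaks to an injection x species area matrix
#'
#' @param annotated Annotated peaks (`injection_id`, `name`, `area`).
#' @param species Column order (species names).
#' @param injections Row order (injection ids).
#' @return Numeric matrix, NA where a species was not observed.
#' @export
area_matrix <- function(annotated, species, injections) {
  m <- matrix(NA_real_, nrow = length(injections), ncol = length(species),
              dimnames = list(injections, species))
  ri <- match(annotated$injection_id, injections)
  ci <- match(annotated$name, species)
  ok <- !is.na(ri) & !is.na(ci)
  m[cbind(ri[ok], ci[ok])] <- annotated$area[ok]
  m
}

#' Write / read a concentration table CSV
#'
#' Leading metadata columns (`sample_id`, `group`, `age`, `sex`, `batch`,
#' `injection_order` when present) followed by one column per canonical
#' species name, cells in nM.
#'
#' @param x Concentration table data frame.
#' @param path File path.
#' @name concentration_io
#' @export
write_concentration_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname concentration_io
#' @export
read_concentration_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Species columns of a concentration table
#'
#' @param x Concentration table.
#' @param panel Optional panel restricting/ordering the species.
#' @return Character vector of species column names.
#' @export
species_columns <- function(x, panel = NULL) {
  meta <- c("sample_id", "group", "age", "sex", "batch", "injection_order")
  cols <- setdiff(names(x), meta)
  if (!is.null(panel)) cols <- intersect(panel$name, cols)
  cols
}
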