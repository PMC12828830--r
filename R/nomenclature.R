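# Sphingolipid shorthand nomenclature: parsing, formatting, structural
# classification. Grammar is the shorthand-2020 dialect
#   "<Class> <C>:<db>;O<n>/<C>:<db>[;O][(d<k>)]"
# e.g. "HexCer 18:1;O2/24:0". The legacy dialect "Cer d18:1/24:0"
# (d = di-, t = tri-hydroxy base; "h24:0" = 2-hydroxy acyl) is accepted on
# parse and normalised to the canonical form.

# head-group composition: hexoses, HexNAc, NeuAc counts are fixed per class
.head_groups <- data.frame(
  class_label = c("Cer", "HexCer", "Hex2Cer", "Hex3Cer", "HexNAcHex3Cer", "GM3"),
  hexoses     = c(0L, 1L, 2L, 3L, 3L, 2L),
  hexnac      = c(0L, 0L, 0L, 0L, 1L, 0L),
  neuac       = c(0L, 0L, 0L, 0L, 0L, 1L),
  stringsAsFactors = FALSE
)

#' Supported head-group classes
#'
#' @return Data frame of supported polar head-group classes with their fixed
#'   glycan composition (hexose, N-acetylhexosamine, N-acetylneuraminic acid
#'   counts relative to the ceramide core).
#' @export
head_group_classes <- function() .head_groups

# base kind is a pure function of (double_bonds, hydroxyls)
.base_kind <- function(db, oh) {
  kind <- rep(NA_character_, length(db))
  kind[db == 1L & oh == 2L] <- "SPH"
  kind[db == 2L & oh == 2L] <- "SPD"
  kind[db == 0L & oh == 2L] <- "DHS"
  kind[db == 0L & oh == 3L] <- "PHS"
  kind
}

.stop_parse <- function(name, token, why) {
  stop(sprintf("cannot parse species name '%s': %s ('%s')", name, why, token),
       call. = FALSE)
}

.check_base <- function(name, c, db, oh) {
  if (c < 14L || c > 22L)
    .stop_parse(name, paste0(c, ":"), "sphingoid-base carbons outside [14, 22]")
  if (db < 0L || db > 2L)
    .stop_parse(name, paste0(":", db), "sphingoid-base double bonds outside [0, 2]")
  if (!oh %in% c(2L, 3L))
    .stop_parse(name, paste0(";O", oh), "sphingoid-base hydroxyls must be 2 or 3")
}

.check_acyl <- function(name, c, db, oh) {
  if (c < 12L || c > 26L)
    .stop_parse(name, paste0(c, ":"), "acyl carbons outside [12, 26]")
  if (db < 0L || db > 3L)
    .stop_parse(name, paste0(":", db), "acyl double bonds outside [0, 3]")
  if (oh > 1L)
    .stop_parse(name, ";O", "acyl hydroxyls must be 0 or 1")
}

#' Parse a sphingolipid shorthand name
#'
#' Parses one species name in shorthand-2020 form
#' (`"Cer 18:1;O2/24:0"`) or the legacy form (`"Cer d18:1/24:0"`,
#' `"Cer d18:1/h24:0"`), returning the structured identity. A trailing
#' `"(d<k>)"` records k deuterium atoms (internal-standard labels); the label
#' does not affect classification.
#'
#' @param name Single species name.
#' @return An object of class `sphingolipid_species`: a list with elements
#'   `name` (canonical form), `head_class`, `base_c`, `base_db`, `base_oh`,
#'   `base_kind` (`SPH`/`SPD`/`DHS`/`PHS`), `acyl_c`, `acyl_db`, `acyl_oh`,
#'   `deuterium` and `subclass`.
#' @examples
#' parse_species_name("HexCer 18:1;O2/24:0")
#' parse_species_name("Cer d18:0/16:0")$subclass  # "DHS-Cer"
#' @export
parse_species_name <- function(name) {
  if (length(name) != 1L || !is.character(name) || is.na(name) || !nzchar(trimws(name)))
    stop("'name' must be a single non-empty character string", call. = FALSE)
  raw <- name
  x <- gsub("\\s+", " ", trimws(name))
  x <- gsub(" ?/ ?", "/", x)

  m <- regmatches(x, regexec("^(\\S+) (.+)$", x))[[1]]
  if (length(m) == 0L) .stop_parse(raw, x, "expected '<Class> <base>/<acyl>'")
  cls <- m[2]; rest <- m[3]
  if (!cls %in% .head_groups$class_label)
    stop(sprintf("unsupported head-group class '%s' in '%s'", cls, raw), call. = FALSE)

  deut <- 0L
  dm <- regmatches(rest, regexec("^(.*)\\(d([0-9]+)\\)$", rest))[[1]]
  if (length(dm)) { rest <- dm[2]; deut <- as.integer(dm[3]) }

  parts <- strsplit(rest, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    .stop_parse(raw, rest, "missing or extra '/' between base and acyl segments")

  # sphingoid base: "18:1;O2" or legacy "d18:1" / "t18:0"
  b <- regmatches(parts[1], regexec("^([0-9]+):([0-9]+);O([0-9]+)$", parts[1]))[[1]]
  if (length(b)) {
    bc <- as.integer(b[2]); bdb <- as.integer(b[3]); boh <- as.integer(b[4])
  } else {
    b <- regmatches(parts[1], regexec("^([dt])([0-9]+):([0-9]+)$", parts[1]))[[1]]
    if (!length(b)) .stop_parse(raw, parts[1], "malformed sphingoid-base segment")
    bc <- as.integer(b[3]); bdb <- as.integer(b[4])
    boh <- if (b[2] == "d") 2L else 3L
  }
  .check_base(raw, bc, bdb, boh)
  kind <- .base_kind(bdb, boh)
  if (is.na(kind))
    .stop_parse(raw, parts[1], "no sphingoid-base kind for this double-bond/hydroxyl combination")

  # acyl chain: "24:0" / "24:1;O" or legacy "h24:0"
  a <- regmatches(parts[2], regexec("^([0-9]+):([0-9]+)(;O)?$", parts[2]))[[1]]
  if (length(a)) {
    ac <- as.integer(a[2]); adb <- as.integer(a[3])
    aoh <- if (nzchar(a[4])) 1L else 0L
  } else {
    a <- regmatches(parts[2], regexec("^h([0-9]+):([0-9]+)$", parts[2]))[[1]]
    if (!length(a)) .stop_parse(raw, parts[2], "malformed acyl segment")
    ac <- as.integer(a[2]); adb <- as.integer(a[3]); aoh <- 1L
  }
  .check_acyl(raw, ac, adb, aoh)

  sp <- structure(list(
    head_class = cls,
    base_c = bc, base_db = bdb, base_oh = boh, base_kind = kind,
    acyl_c = ac, acyl_db = adb, acyl_oh = aoh,
    deuterium = deut
  ), class = "sphingolipid_species")
  sp$subclass <- species_subclass(sp)
  sp$name <- format_species_name(sp)
  sp
}

#' Format a species to its canonical shorthand name
#'
#' Inverse of [parse_species_name()]: `parse(format(x))` is the identity on
#' valid species.
#'
#' @param species A `sphingolipid_species` object (or a bare list with the
#'   same fields).
#' @return Canonical shorthand name, e.g. `"GM3 18:1;O2/24:1"`.
#' @export
format_species_name <- function(species) {
  acyl <- sprintf("%d:%d%s", species$acyl_c, species$acyl_db,
                  if (species$acyl_oh > 0L) ";O" else "")
  lab <- if (!is.null(species$deuterium) && species$deuterium > 0L)
    sprintf("(d%d)", species$deuterium) else ""
  sprintf("%s %d:%d;O%d/%s%s", species$head_class,
          species$base_c, species$base_db, species$base_oh, acyl, lab)
}

#' @export
print.sphingolipid_species <- function(x, ...) {
  cat(sprintf("<sphingolipid species> %s  [subclass %s, base %s, acyl C%d%s]\n",
              x$name, x$subclass, classify_spb(x),
              x$acyl_c, if (x$acyl_oh) " (2-OH)" else ""))
  invisible(x)
}

#' Subclass label of a species
#'
#' Ceramides split by base kind (`Cer` for SPH/SPD bases, `DHS-Cer`,
#' `PHS-Cer`); glycosphingolipid classes keep their head-group label.
#'
#' @param species A `sphingolipid_species`.
#' @return Subclass label.
#' @export
species_subclass <- function(species) {
  if (species$head_class == "Cer") {
    switch(species$base_kind,
           SPH = "Cer", SPD = "Cer",
           DHS = "DHS-Cer", PHS = "PHS-Cer")
  } else species$head_class
}

#' Sphingoid-base class label
#'
#' @param species A `sphingolipid_species`.
#' @param merged If `TRUE`, SPH and SPD bases of equal chain length share the
#'   merged label `"C<n>-SPH/D"` (the view used for base-resolved
#'   aggregations); the merge is a view flag, not a loss of information.
#' @return Label such as `"C18-SPH"`, `"C18-SPH/D"`, `"C18-DHS"`.
#' @export
classify_spb <- function(species, merged = FALSE) {
  kind <- species$base_kind
  if (merged && kind %in% c("SPH", "SPD")) kind <- "SPH/D"
  sprintf("C%d-%s", species$base_c, kind)
}

#' N-acyl chain class label
#'
#' Pools saturations: all C24:x chains map to `"C24"`. The hydroxylation flag
#' is carried separately (`attr(, "hydroxyl")`).
#'
#' @param species A `sphingolipid_species`.
#' @return Label `"C<n>"` with attribute `hydroxyl` (logical).
#' @export
classify_acyl <- function(species) {
  structure(sprintf("C%d", species$acyl_c), hydroxyl = species$acyl_oh > 0L)
}

#' Parse many species names into a panel table
#'
#' Vectorised driver over [parse_species_name()]; the returned table is the
#' panel representation used by every downstream aggregation.
#'
#' @param names Character vector of species names (either dialect).
#' @return Data frame with one row per name: canonical `name`, `head_class`,
#'   base fields and `base_kind`, acyl fields, `deuterium`, `subclass`,
#'   `spb` (`"C18-SPH"` style), `spb_merged` (`"C18-SPH/D"` style),
#'   `acyl` (`"C24"`), `acyl_hydroxyl`.
#' @export
parse_species_names <- function(names) {
  sps <- lapply(names, parse_species_name)
  data.frame(
    name = vapply(sps, `[[`, "", "name"),
    head_class = vapply(sps, `[[`, "", "head_class"),
    base_c = vapply(sps, `[[`, 0L, "base_c"),
    base_db = vapply(sps, `[[`, 0L, "base_db"),
    base_oh = vapply(sps, `[[`, 0L, "base_oh"),
    base_kind = vapply(sps, `[[`, "", "base_kind"),
    acyl_c = vapply(sps, `[[`, 0L, "acyl_c"),
    acyl_db = vapply(sps, `[[`, 0L, "acyl_db"),
    acyl_oh = vapply(sps, `[[`, 0L, "acyl_oh"),
    deuterium = vapply(sps, `[[`, 0L, "deuterium"),
    subclass = vapply(sps, `[[`, "", "subclass"),
    spb = vapply(sps, classify_spb, ""),
    spb_merged = vapply(sps, classify_spb, "", merged = TRUE),
    acyl = vapply(sps, function(s) as.character(classify_acyl(s)), ""),
    acyl_hydroxyl = vapply(sps, function(s) isTRUE(attr(classify_acyl(s), "hydroxyl")), NA),
    stringsAsFactors = FALSE
  )
}

#' Write / read a panel file
#'
#' Plain-CSV exchange format for the species panel; the writer emits
#' canonical names only.
#'
#' @param panel Panel data frame (from [parse_species_names()] or
#'   [generate_panel()]), must carry `name` and `quant_level` columns.
#' @param path File path.
#' @return `read_panel` returns the panel table re-parsed from the stored
#'   names (so the structural columns are always consistent with the names).
#' @export
write_panel <- function(panel, path) {
  stopifnot(all(c("name", "quant_level") %in% names(panel)))
  out <- data.frame(name = panel$name,
                    head_class = panel$head_class,
                    spb = panel$spb,
                    acyl = panel$acyl,
                    quant_level = panel$quant_level)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  panel <- parse_species_names(raw$name)
  panel$quant_level <- if ("quant_level" %in% names(raw)) as.integer(raw$quant_level)
                       else assign_quant_level(panel)
  panel
}
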