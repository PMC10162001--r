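# Ontology cross-reference loading and the filtered UMLS->ORDO and
# ICD-9->ORDO concept maps.
#
# A cross-reference is a triple <ORDO concept, external concept, relation>.
# Only E (exact) and BTNT (broader-to-narrower) relations are trusted by
# default, NTBT relations (a broader external concept standing for a narrow
# rare disease, e.g. common hyperlipidemia for a rare hyperlipidemia) are
# dropped, and ORDO concepts sitting under the "group of disorders" phenome
# class are filtered out — both filters exist to stop common-disease
# concepts being read as rare-disease evidence.

KNOWN_RELATIONS <- c("E", "BTNT", "NTBT")

#' Load an ontology cross-reference table
#'
#' Tab-separated, UTF-8, header row required with columns `source_id`,
#' `target_id`, `target_system`, `relation`. Relations are upper-cased and
#' unknown tokens map to `"other"`; rows with an empty id are skipped with a
#' message giving the count.
#'
#' @param path TSV path.
#' @return A data.frame of cross-references (class `crossref`).
#' @export
load_crossref_table <- function(path) {
  if (!file.exists(path)) stop("cross-reference file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          colClasses = "character")
  needed <- c("source_id", "target_id", "target_system", "relation")
  for (col in needed) {
    if (!col %in% names(df)) {
      stop("cross-reference table ", path, " is missing column '", col, "'")
    }
  }
  crossref(df$source_id, df$target_id, df$target_system, df$relation)
}

#' Construct a cross-reference table
#'
#' @param source_id ORDO concept ids (e.g. "Orphanet_3325").
#' @param target_id External concept ids (UMLS CUIs upper-cased, ICD codes
#'   kept verbatim including the dot).
#' @param target_system "UMLS" or "ICD10".
#' @param relation Relation tokens; normalised to upper case, anything
#'   outside E/BTNT/NTBT becomes "other".
#' @return A data.frame with class `crossref`.
#' @export
crossref <- function(source_id, target_id, target_system, relation) {
  df <- data.frame(source_id = trimws2(source_id),
                   target_id = trimws2(target_id),
                   target_system = toupper(trimws2(target_system)),
                   relation = toupper(trimws2(relation)),
                   stringsAsFactors = FALSE)
  df$target_id <- ifelse(df$target_system == "UMLS",
                         toupper(df$target_id), df$target_id)
  df$relation[!(df$relation %in% KNOWN_RELATIONS)] <- "other"
  empty <- !nzchar(df$source_id) | !nzchar(df$target_id)
  if (any(empty)) {
    message("dropped ", sum(empty), " cross-reference row(s) with empty ids")
    df <- df[!empty, , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("crossref", "data.frame")
  df
}

#' Load the ORDO metadata table
#'
#' Columns `ordo_id`, `label`, `is_group_of_disorders` (true/false). The
#' group-of-disorders flag marks umbrella concepts under the ORDO phenome
#' class whose external mappings point at common diseases.
#'
#' @param path TSV path.
#' @return A data.frame with one row per ORDO concept.
#' @export
load_ordo_meta <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  needed <- c("ordo_id", "label", "is_group_of_disorders")
  for (col in needed) {
    if (!col %in% names(df)) {
      stop("ORDO metadata table ", path, " is missing column '", col, "'")
    }
  }
  ordo_meta(df$ordo_id, df$label, df$is_group_of_disorders)
}

#' Construct an ORDO metadata table
#' @param ordo_id ORDO ids ("Orphanet_<digits>").
#' @param label Concept labels.
#' @param is_group_of_disorders Logical (or "true"/"false") flags.
#' @return A data.frame, one row per unique ORDO id.
#' @export
ordo_meta <- function(ordo_id, label, is_group_of_disorders) {
  df <- data.frame(ordo_id = trimws2(ordo_id), label = as.character(label),
                   is_group_of_disorders =
                     tolower(trimws2(is_group_of_disorders)) %in% c("true", "t", "1"),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$ordo_id)) stop("duplicate ordo_id in ORDO metadata")
  if (any(!nzchar(df$ordo_id))) stop("empty ordo_id in ORDO metadata")
  df
}

#' Load a two-column pair table (e.g. ICD-9 to ICD-10)
#' @param path TSV path with a header row and two columns (source, target).
#' @return A data.frame with columns `source`, `target`.
#' @export
load_pair_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          colClasses = "character")
  if (ncol(df) < 2) stop("pair table ", path, " needs two columns")
  out <- data.frame(source = trimws2(df[[1]]), target = trimws2(df[[2]]),
                    stringsAsFactors = FALSE)
  out[nzchar(out$source) & nzchar(out$target), , drop = FALSE]
}

#' Build the filtered UMLS-to-ORDO concept map
#'
#' Keeps UMLS-system cross-references whose relation is in
#' `allowed_relations` (default exact matches and broader-to-narrower, i.e.
#' E and BTNT; NTBT is excluded), drops ORDO ids absent from the metadata
#' table (counted in a message), and, when `drop_groups`, excludes ORDO
#' concepts flagged as groups of disorders. The key set of the resulting map
#' is the rare-disease UMLS vocabulary O^rare_UMLS.
#'
#' @param xrefs A [crossref()] table.
#' @param meta An [ordo_meta()] table.
#' @param allowed_relations Relation tokens to trust (default `c("E","BTNT")`).
#' @param drop_groups Exclude group-of-disorders ORDO concepts (default TRUE).
#' @return A `umls_ordo_map`.
#' @export
build_umls_to_ordo_map <- function(xrefs, meta,
                                   allowed_relations = c("E", "BTNT"),
                                   drop_groups = TRUE) {
  x <- xrefs[xrefs$target_system == "UMLS" &
               xrefs$relation %in% toupper(allowed_relations), , drop = FALSE]
  unknown <- !(x$source_id %in% meta$ordo_id)
  if (any(unknown)) {
    message("dropped ", sum(unknown),
            " cross-reference(s) whose ORDO id lacks metadata")
    x <- x[!unknown, , drop = FALSE]
  }
  if (drop_groups) {
    groups <- meta$ordo_id[meta$is_group_of_disorders]
    x <- x[!(x$source_id %in% groups), , drop = FALSE]
  }
  entries <- if (nrow(x) == 0) {
    stats::setNames(list(), character(0))
  } else {
    lapply(split(x$source_id, x$target_id), function(v) sort(unique(v)))
  }
  structure(list(entries = entries), class = "umls_ordo_map")
}

#' The rare-disease UMLS vocabulary of a map
#' @param map A `umls_ordo_map`.
#' @return Character vector of UMLS ids (the map's key set, O^rare_UMLS).
#' @export
rare_umls_set <- function(map) {
  stopifnot(inherits(map, "umls_ordo_map"))
  names(map$entries)
}

#' @export
print.umls_ordo_map <- function(x, ...) {
  cat("<umls_ordo_map> ", length(x$entries), " UMLS concept(s) -> ",
      length(unique(unlist(x$entries))), " ORDO concept(s)\n", sep = "")
  invisible(x)
}

#' Map one UMLS concept to ORDO
#' @param umls_id A UMLS id.
#' @param map A `umls_ordo_map`.
#' @return Character vector of ORDO ids (empty when unmapped).
#' @export
map_umls_to_ordo <- function(umls_id, map) {
  stopifnot(inherits(map, "umls_ordo_map"))
  hit <- map$entries[[toupper(trimws2(umls_id))]]
  if (is.null(hit)) character(0) else hit
}

#' Build the ICD-9-to-ORDO baseline map
#'
#' Composes two paths and unions them per ICD-9 code: (i) ICD-9 -> ICD-10
#' pairs composed with ICD10-system cross-references (same relation and
#' group filtering as the UMLS map), and (ii) ICD-9 -> UMLS pairs composed
#' with the UMLS-to-ORDO map. Per-entry provenance records which path(s)
#' fired.
#'
#' @param icd9_to_icd10 Pair table (`source` = ICD-9, `target` = ICD-10).
#' @param icd9_to_umls Pair table (`source` = ICD-9, `target` = UMLS).
#' @param ordo_xrefs A [crossref()] table holding both UMLS and ICD10 rows.
#' @param meta An [ordo_meta()] table.
#' @param allowed_relations,drop_groups As in [build_umls_to_ordo_map()].
#' @return An `icd9_ordo_map` with `entries` (ICD-9 code -> ORDO ids) and
#'   `provenance` (ICD-9 code -> subset of `c("via_icd10", "via_umls")`).
#' @export
build_icd9_to_ordo_map <- function(icd9_to_icd10, icd9_to_umls, ordo_xrefs,
                                   meta, allowed_relations = c("E", "BTNT"),
                                   drop_groups = TRUE) {
  # ICD-10 -> ORDO lookup under the same filters as the UMLS map
  x10 <- ordo_xrefs[ordo_xrefs$target_system == "ICD10" &
                      ordo_xrefs$relation %in% toupper(allowed_relations), ,
                    drop = FALSE]
  x10 <- x10[x10$source_id %in% meta$ordo_id, , drop = FALSE]
  if (drop_groups) {
    groups <- meta$ordo_id[meta$is_group_of_disorders]
    x10 <- x10[!(x10$source_id %in% groups), , drop = FALSE]
  }
  icd10_map <- if (nrow(x10) == 0) list() else
    lapply(split(x10$source_id, x10$target_id), function(v) sort(unique(v)))
  umap <- build_umls_to_ordo_map(ordo_xrefs, meta,
                                 allowed_relations = allowed_relations,
                                 drop_groups = drop_groups)
  entries <- list(); provenance <- list()
  add <- function(code, ordos, via) {
    if (length(ordos) == 0) return()
    entries[[code]] <<- sort(unique(c(entries[[code]], ordos)))
    provenance[[code]] <<- sort(unique(c(provenance[[code]], via)))
  }
  if (nrow(icd9_to_icd10) > 0) {
    for (i in seq_len(nrow(icd9_to_icd10))) {
      add(icd9_to_icd10$source[i], icd10_map[[icd9_to_icd10$target[i]]], "via_icd10")
    }
  }
  if (nrow(icd9_to_umls) > 0) {
    for (i in seq_len(nrow(icd9_to_umls))) {
      add(icd9_to_umls$source[i],
          map_umls_to_ordo(icd9_to_umls$target[i], umap), "via_umls")
    }
  }
  structure(list(entries = entries, provenance = provenance),
            class = "icd9_ordo_map")
}

#' @export
print.icd9_ordo_map <- function(x, ...) {
  cat("<icd9_ordo_map> ", length(x$entries), " ICD-9 code(s) -> ",
      length(unique(unlist(x$entries))), " ORDO concept(s)\n", sep = "")
  invisible(x)
}

#' Map one ICD-9 code to ORDO
#' @param icd9_code An ICD-9 code (verbatim, including the dot).
#' @param map An `icd9_ordo_map`.
#' @return Character vector of ORDO ids (empty when unmapped).
#' @export
map_icd9_to_ordo <- function(icd9_code, map) {
  stopifnot(inherits(map, "icd9_ordo_map"))
  hit <- map$entries[[trimws2(icd9_code)]]
  if (is.null(hit)) character(0) else hit
}
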