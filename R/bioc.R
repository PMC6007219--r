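# All offsets in this package are 0-based, half-open, and counted in Unicode
# code points.  R's substr() on UTF-8 strings counts code points, which is the
# canonical unit here; every input string is forced through enc2utf8().

slice_cp <- function(text, start, end) {
  # [start, end) in 0-based code points
  if (end <= start) return("")
  substr(text, start + 1L, end)
}

ncp <- function(text) nchar(text, type = "chars")

#' Create a span annotation
#'
#' A single annotated mention with document-global, 0-based, half-open
#' code-point offsets.  Organism annotations carry either a taxonomy ID
#' (`taxon_id`) or a type-only label (`type_only_label`, e.g. `"bacteria"`
#' for mentions annotated as an organism without a database link), never both.
#'
#' @param start,end Document-global code-point offsets, half-open.
#' @param surface The annotated text as it appears in the passage.
#' @param entity_type Annotation type, default `"organism"`.
#' @param taxon_id Integer NCBI Taxonomy ID, or `NULL`.
#' @param type_only_label Free-text organism type when no ID is assigned.
#' @param id Optional annotation identifier (kept through serialization).
#' @return An object of class `span_annotation`.
#' @export
span_annotation <- function(start, end, surface, entity_type = "organism",
                            taxon_id = NULL, type_only_label = NULL,
                            id = NULL) {
  stopifnot(start >= 0, end > start)
  if (!is.null(taxon_id) && !is.null(type_only_label))
    stop("an annotation carries either a taxon_id or a type_only_label, not both")
  structure(list(
    id = if (is.null(id)) NA_character_ else as.character(id),
    start = as.integer(start), end = as.integer(end),
    surface = enc2utf8(as.character(surface)),
    entity_type = entity_type,
    taxon_id = if (is.null(taxon_id)) NULL else as.integer(taxon_id),
    type_only_label = type_only_label,
    flagged = FALSE
  ), class = "span_annotation")
}

#' Create a BioC passage
#'
#' @param offset 0-based code-point offset of the passage text within the
#'   document's concatenated text.
#' @param text Passage text (figure caption or full-text section).
#' @param section_label Section tag such as `"introduction"`, `"abstract"`,
#'   `"fig_caption"`; free text otherwise.
#' @param annotations List of [span_annotation()] objects.
#' @return An object of class `bioc_passage`.
#' @export
bioc_passage <- function(offset, text, section_label = "other",
                         annotations = list()) {
  stopifnot(offset >= 0)
  structure(list(
    offset = as.integer(offset),
    text = enc2utf8(as.character(text)),
    section_label = section_label,
    annotations = annotations
  ), class = "bioc_passage")
}

#' Create a BioC document
#' @param doc_id Document identifier, unique within a collection.
#' @param passages List of [bioc_passage()] objects, offsets strictly increasing.
#' @return An object of class `bioc_document`.
#' @export
bioc_document <- function(doc_id, passages = list()) {
  offs <- vapply(passages, function(p) p$offset, integer(1))
  if (length(offs) > 1 && any(diff(offs) <= 0))
    stop("passage offsets must be strictly increasing in document ", doc_id)
  structure(list(doc_id = as.character(doc_id), passages = passages),
            class = "bioc_document")
}

#' Create a BioC collection
#' @param source_id Collection source string.
#' @param documents List of [bioc_document()] objects with unique `doc_id`s.
#' @return An object of class `bioc_collection`.
#' @export
bioc_collection <- function(source_id = "captaxa", documents = list()) {
  ids <- vapply(documents, function(d) d$doc_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate document identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(list(source_id = source_id, documents = documents),
            class = "bioc_collection")
}

#' @export
print.bioc_collection <- function(x, ...) {
  np <- sum(vapply(x$documents, function(d) length(d$passages), integer(1)))
  na <- sum(vapply(x$documents, function(d)
    sum(vapply(d$passages, function(p) length(p$annotations), integer(1))),
    integer(1)))
  cat(sprintf("<bioc_collection '%s': %d document(s), %d passage(s), %d annotation(s)>\n",
              x$source_id, length(x$documents), np, na))
  invisible(x)
}

passage_slice <- function(p, start, end) {
  slice_cp(p$text, start - p$offset, end - p$offset)
}

ann_consistent <- function(p, a) {
  identical(passage_slice(p, a$start, a$end), a$surface)
}

# ---------------------------------------------------------------------------
# Reading

xml_infons <- function(node) {
  inf <- xml2::xml_find_all(node, "./infon")
  stats::setNames(as.list(xml2::xml_text(inf)),
                  xml2::xml_attr(inf, "key"))
}

parse_taxon_infons <- function(infons) {
  # canonical: key "NCBI taxon" -> "9606"; also accepted: the Bio-ID style
  # type infon "NCBI taxon:9606" and key "NCBI Taxonomy ID"
  taxon_id <- NULL; type_only <- NULL; etype <- "organism"
  ty <- infons[["type"]]
  if (!is.null(ty)) {
    if (grepl("^NCBI +taxon:", ty, ignore.case = TRUE)) {
      taxon_id <- as.integer(sub("^NCBI +taxon:\\s*", "", ty, ignore.case = TRUE))
    } else if (grepl("^organism:", ty)) {
      type_only <- trimws(sub("^organism:", "", ty))
    } else {
      etype <- ty
    }
  }
  for (k in c("NCBI taxon", "NCBI Taxonomy ID")) {
    if (!is.null(infons[[k]])) taxon_id <- as.integer(infons[[k]])
  }
  if (!is.null(infons[["organism_type"]])) type_only <- infons[["organism_type"]]
  list(taxon_id = taxon_id, type_only_label = type_only, entity_type = etype)
}

parse_annotation <- function(node) {
  infons <- xml_infons(node)
  loc <- xml2::xml_find_first(node, "./location")
  if (inherits(loc, "xml_missing"))
    stop("annotation without a location element")
  off <- as.integer(xml2::xml_attr(loc, "offset"))
  len <- as.integer(xml2::xml_attr(loc, "length"))
  surface <- xml2::xml_text(xml2::xml_find_first(node, "./text"))
  parsed <- parse_taxon_infons(infons)
  a <- span_annotation(off, off + len, surface,
                       entity_type = parsed$entity_type,
                       taxon_id = parsed$taxon_id,
                       type_only_label = parsed$type_only_label,
                       id = xml2::xml_attr(node, "id"))
  a
}

parse_passage <- function(node) {
  infons <- xml_infons(node)
  label <- infons[["section_label"]]
  if (is.null(label)) label <- infons[["type"]]
  if (is.null(label)) label <- "other"
  off <- as.integer(xml2::xml_text(xml2::xml_find_first(node, "./offset")))
  txt_node <- xml2::xml_find_first(node, "./text")
  txt <- if (inherits(txt_node, "xml_missing")) "" else xml2::xml_text(txt_node)
  anns <- lapply(xml2::xml_find_all(node, "./annotation"), parse_annotation)
  bioc_passage(off, txt, section_label = label, annotations = anns)
}

#' Read a BioC XML collection
#'
#' Parses a BioC collection (the figure-caption dialect of the Bio-ID track)
#' into a [bioc_collection()].  All offsets are interpreted as 0-based Unicode
#' code-point indices; the collection-level infon `offset_unit`, when present,
#' must name that unit (`"codepoint"` / `"unicode"`), otherwise reading stops
#' with an error rather than guessing.
#'
#' @param xml_text A string of BioC XML, or a file path.
#' @return A [bioc_collection()].
#' @export
read_collection <- function(xml_text) {
  doc <- tryCatch(xml2::read_xml(xml_text),
                  error = function(e) stop("BioC parse error: ",
                                           conditionMessage(e), call. = FALSE))
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "collection")
    stop("expected a <collection> root element, found <",
         xml2::xml_name(root), ">")
  cinfons <- xml_infons(root)
  unit <- cinfons[["offset_unit"]]
  if (!is.null(unit) && !tolower(unit) %in% c("codepoint", "code_point", "unicode"))
    stop("unsupported offset unit '", unit,
         "': this reader only handles Unicode code-point offsets")
  src <- xml2::xml_text(xml2::xml_find_first(root, "./source"))
  if (is.na(src)) src <- ""
  docs <- lapply(xml2::xml_find_all(root, "./document"), function(d) {
    did <- xml2::xml_text(xml2::xml_find_first(d, "./id"))
    bioc_document(did, lapply(xml2::xml_find_all(d, "./passage"), parse_passage))
  })
  bioc_collection(source_id = src, documents = docs)
}

# ---------------------------------------------------------------------------
# Writing

write_annotation_node <- function(parent, a, p) {
  if (!is.null(p)) {
    local_start <- a$start - p$offset
    if (local_start < 0 || a$end - p$offset > ncp(p$text))
      stop("annotation span [", a$start, ",", a$end,
           ") lies outside its passage; refusing to serialize")
  }
  an <- xml2::xml_add_child(parent, "annotation")
  if (!is.null(a$id) && !is.na(a$id)) xml2::xml_set_attr(an, "id", a$id)
  xml2::xml_add_child(an, "infon", a$entity_type, key = "type")
  if (!is.null(a$taxon_id))
    xml2::xml_add_child(an, "infon", as.character(a$taxon_id), key = "NCBI taxon")
  if (!is.null(a$type_only_label))
    xml2::xml_add_child(an, "infon", a$type_only_label, key = "organism_type")
  loc <- xml2::xml_add_child(an, "location")
  xml2::xml_set_attr(loc, "offset", as.character(a$start))
  xml2::xml_set_attr(loc, "length", as.character(a$end - a$start))
  xml2::xml_add_child(an, "text", a$surface)
  an
}

#' Write a collection as BioC XML
#'
#' Serializes a [bioc_collection()] to the same BioC dialect that
#' [read_collection()] reads; `read_collection(write_collection(x))`
#' reproduces `x` field for field.  An annotation whose span falls outside its
#' passage raises an error instead of being silently emitted.
#'
#' @param collection A [bioc_collection()].
#' @param file Optional path; when given the XML is also written to disk.
#' @return The XML as a single string (invisibly when `file` is given).
#' @export
write_collection <- function(collection, file = NULL) {
  stopifnot(inherits(collection, "bioc_collection"))
  root <- xml2::xml_new_root("collection")
  xml2::xml_add_child(root, "source", collection$source_id)
  xml2::xml_add_child(root, "infon", "codepoint", key = "offset_unit")
  for (d in collection$documents) {
    dn <- xml2::xml_add_child(root, "document")
    xml2::xml_add_child(dn, "id", d$doc_id)
    for (p in d$passages) {
      pn <- xml2::xml_add_child(dn, "passage")
      xml2::xml_add_child(pn, "infon", p$section_label, key = "section_label")
      xml2::xml_add_child(pn, "offset", as.character(p$offset))
      xml2::xml_add_child(pn, "text", p$text)
      for (a in p$annotations) write_annotation_node(pn, a, p)
    }
  }
  out <- as.character(root)
  if (!is.null(file)) {
    writeLines(out, file, useBytes = TRUE)
    return(invisible(out))
  }
  out
}

# ---------------------------------------------------------------------------
# Span repair

#' Repair annotation spans shifted by Unicode-offset inconsistencies
#'
#' Source corpora occasionally declare annotation offsets in the wrong unit
#' (bytes or UTF-16 units instead of code points), so spans near characters
#' like "α" no longer slice to their surface text.  For every annotation
#' whose declared span does not reproduce its surface, the span is moved to
#' the nearest occurrence of the surface within `search_window` code points of
#' the declared start.  Already-consistent annotations are left untouched;
#' annotations whose surface cannot be found in the window are flagged
#' (`flagged = TRUE`), never dropped.
#'
#' @param passage A [bioc_passage()] whose annotations carry surface text.
#' @param search_window Maximum shift, in code points (default 10).
#' @return The repaired passage; attribute `n_flagged` counts annotations that
#'   could not be repaired.
#' @export
repair_annotation_spans <- function(passage, search_window = 10L) {
  stopifnot(inherits(passage, "bioc_passage"))
  n_flagged <- 0L
  passage$annotations <- lapply(passage$annotations, function(a) {
    if (ann_consistent(passage, a)) return(a)
    want <- a$surface
    wlen <- ncp(want)
    declared_local <- a$start - passage$offset
    best <- NA_integer_
    for (delta in 0:search_window) {
      for (cand in unique(c(declared_local - delta, declared_local + delta))) {
        if (cand < 0 || cand + wlen > ncp(passage$text)) next
        if (identical(slice_cp(passage$text, cand, cand + wlen), want)) {
          best <- cand; break
        }
      }
      if (!is.na(best)) break
    }
    if (is.na(best)) {
      a$flagged <- TRUE
      n_flagged <<- n_flagged + 1L
    } else {
      a$start <- as.integer(passage$offset + best)
      a$end <- as.integer(a$start + wlen)
      a$flagged <- FALSE
    }
    a
  })
  attr(passage, "n_flagged") <- n_flagged
  passage
}
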