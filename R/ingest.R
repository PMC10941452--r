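# Document and concept-registry readers. All readers are UTF-8 only, strip a
# leading BOM, and never normalize text: section text is the file's content
# byte-for-byte after decoding, so stand-off offsets stay valid.

read_utf8 <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) >= 3 && identical(raw[1:3], as.raw(c(0xEF, 0xBB, 0xBF))))
    raw <- raw[-(1:3)]
  txt <- rawToChar(raw)
  Encoding(txt) <- "UTF-8"
  if (!validUTF8(txt)) abort_domain("'%s' is not valid UTF-8", path)
  txt
}

#' Read a plain-text document
#'
#' One document per file: a single section named `"text"` holding the file
#' content verbatim (trailing newlines included — no silent normalization),
#' with `document_id` the file stem.
#'
#' @param path Path to a UTF-8 text file.
#' @return A document (see [new_document()]).
#' @export
read_txt_document <- function(path) {
  txt <- read_utf8(path)
  if (!nzchar(txt)) abort_domain("'%s' is empty", path)
  new_document(tools::file_path_sans_ext(basename(path)), c(text = txt))
}

#' Read tabular documents from CSV
#'
#' One document per row. A column literally named `id` (case-insensitive)
#' supplies document ids; otherwise the first column does, with a warning.
#' Every other header becomes a section, in header order. Empty cells yield
#' present-but-empty sections (annotation is impossible on empty text).
#' Dialect: comma-separated, double-quote quoting, header mandatory.
#'
#' @param path Path to a CSV file.
#' @return List of documents.
#' @export
read_csv_documents <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        fileEncoding = "UTF-8")
  if (ncol(df) < 2L) abort_domain("'%s' needs an id column and at least one section column", path)
  idcol <- which(tolower(names(df)) == "id")
  if (length(idcol) == 0L) {
    idcol <- 1L
    warning(sprintf("no 'id' column in '%s'; using first column '%s' as id",
                    path, names(df)[1]))
  } else idcol <- idcol[[1]]
  ids <- df[[idcol]]
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    abort_domain("duplicate document id(s) in '%s': %s", path,
                 paste(unique(dup), collapse = ", "))
  sections <- setdiff(seq_along(df), idcol)
  lapply(seq_len(nrow(df)), function(i) {
    secs <- vapply(sections, function(j) df[i, j], character(1))
    names(secs) <- names(df)[sections]
    secs[is.na(secs)] <- ""
    new_document(ids[[i]], secs)
  })
}

#' Read documents from JSON
#'
#' The top level is one record or a list of records of string fields; keys
#' become sections in insertion order. An `id` key supplies the document id;
#' otherwise an ordinal id `doc-000001`, ... is synthesized. Nested values are
#' an error (flat records only).
#'
#' @param path Path to a JSON file.
#' @return List of documents.
#' @export
read_json_documents <- function(path) {
  x <- jsonlite::fromJSON(read_utf8(path), simplifyVector = FALSE)
  if (length(x) > 0L && !is.null(names(x))) x <- list(x)
  out <- vector("list", length(x))
  for (i in seq_along(x)) {
    rec <- x[[i]]
    if (!is.list(rec) || is.null(names(rec)))
      abort_domain("record %d is not a key-value object", i)
    for (k in names(rec))
      if (!(is.character(rec[[k]]) && length(rec[[k]]) == 1L))
        abort_domain("record %d: field '%s' is not a string (flat records only)", i, k)
    id <- rec[["id"]] %||% sprintf("doc-%06d", i)
    secs <- unlist(rec[setdiff(names(rec), "id")])
    if (length(secs) == 0L) abort_domain("record %d has no text fields", i)
    out[[i]] <- new_document(id, secs)
  }
  out
}

#' Load a concept registry from CSV or JSON
#'
#' Mirrors the downloadable concept templates: columns/keys `identifier` (or
#' `uri` or `id`), `name`, `type` and optional `description`; identifier, name
#' and type are mandatory on every row (violations are reported with the row
#' number). Duplicate rows collapse if identical and error if conflicting.
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"json"`; default from the file extension.
#' @return A validated concept data frame ready for [register_concepts()].
#' @export
load_concepts <- function(path, format = tolower(tools::file_ext(path))) {
  format <- match.arg(format, c("csv", "json"))
  df <- if (format == "csv") {
    utils::read.csv(path, colClasses = "character", check.names = FALSE,
                    fileEncoding = "UTF-8")
  } else {
    recs <- jsonlite::fromJSON(read_utf8(path), simplifyVector = FALSE)
    if (length(recs) > 0L && !is.null(names(recs))) recs <- list(recs)
    do.call(rbind, lapply(recs, function(r)
      data.frame(lapply(r, function(v) as.character(v %||% "")),
                 stringsAsFactors = FALSE)))
  }
  names(df) <- tolower(names(df))
  idcol <- intersect(c("identifier", "uri", "id"), names(df))
  if (length(idcol) == 0L) abort_domain("no identifier/uri/id column in '%s'", path)
  out <- data.frame(identifier = df[[idcol[[1]]]],
                    name = df[["name"]] %||% NA_character_,
                    type = df[["type"]] %||% NA_character_,
                    description = df[["description"]] %||% "",
                    stringsAsFactors = FALSE)
  out$description[is.na(out$description)] <- ""
  for (i in seq_len(nrow(out))) {
    for (field in c("identifier", "name", "type")) {
      v <- out[[field]][[i]]
      if (is.na(v) || !nzchar(v))
        abort_domain("row %d: %s mandatory", i, field)
    }
  }
  key <- out$identifier
  for (id in unique(key[duplicated(key)])) {
    rows <- out[key == id, ]
    if (nrow(unique(rows)) > 1L)
      abort_domain("conflicting duplicate rows for concept '%s'", id)
  }
  unique(out)
}

#' A fixture-backed bibliographic fetcher
#'
#' Builds a fetcher suitable for [fetch_record()] from a named list of
#' records, emulating PubMed / Semantic Scholar / OpenAIRE responses without
#' network I/O. Each record is a list with `title`, `abstract` and optionally
#' `authors`, `venue`, `publication_date`.
#'
#' @param records Named list keyed by identifier (PMID or DOI).
#' @return A function `(identifier, source) -> record` erroring on a miss.
#' @export
stub_fetcher <- function(records) {
  force(records)
  function(identifier, source) {
    rec <- records[[identifier]]
    if (is.null(rec)) abort_domain("%s: no record for '%s'", source, identifier)
    rec
  }
}

#' Fetch a bibliographic record and map it to a document
#'
#' PubMed requires a PMID (digits); Semantic Scholar and OpenAIRE require a
#' DOI. The transport is injected: pass a live HTTP implementation in
#' production or [stub_fetcher()] in tests. The resulting document has
#' sections `title` and `abstract` (either omitted when empty; at least one
#' must be non-empty) and the remaining fields as metadata. Document ids
#' follow the `<source>_<identifier>` convention, e.g. `pubmed_27839516`.
#'
#' @param identifier PMID or DOI.
#' @param source One of `"pubmed"`, `"semanticscholar"`, `"openaire"`.
#' @param fetcher A function `(identifier, source) -> record`.
#' @return A document.
#' @export
fetch_record <- function(identifier, source = c("pubmed", "semanticscholar", "openaire"),
                         fetcher) {
  source <- match.arg(source)
  assert_string(identifier, "identifier")
  is_pmid <- grepl("^[0-9]+$", identifier)
  if (source == "pubmed" && !is_pmid)
    abort_domain("pubmed requires a PMID, got '%s'", identifier)
  if (source != "pubmed" && is_pmid)
    abort_domain("%s requires a DOI, got PMID '%s'", source, identifier)
  rec <- tryCatch(fetcher(identifier, source), error = function(e)
    abort_domain("%s fetch failed: %s", source, conditionMessage(e)))
  title <- rec$title %||% ""
  abstract <- rec$abstract %||% ""
  if (!nzchar(title) && !nzchar(abstract))
    abort_domain("%s record for '%s' has neither title nor abstract", source,
                 identifier)
  secs <- c(if (nzchar(title)) c(title = title),
            if (nzchar(abstract)) c(abstract = abstract))
  doc_id <- paste0(source, "_", gsub("[^A-Za-z0-9._-]+", "_", identifier))
  new_document(doc_id, secs,
               metadata = list(external_id = identifier,
                               id_kind = if (is_pmid) "pmid" else "doi",
                               title = title, abstract = abstract,
                               authors = rec$authors %||% list(),
                               venue = rec$venue %||% "",
                               publication_date = rec$publication_date %||% ""))
}
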