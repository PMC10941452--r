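#' @keywords internal
"_PACKAGE"

# Field separator for composite identity keys. Unit separator cannot occur in
# section names, concept ids or document ids ingested from text formats.
.SEP <- "\x1f"

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_domain <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c("annostore_error", "error")))
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

assert_string <- function(x, what) {
  if (!is_string(x) || !nzchar(x)) abort_domain("%s must be a non-empty string", what)
  invisible(x)
}

#' Current timestamp in UTC ISO-8601
#'
#' Collections created by the synthetic generators carry a frozen clock so
#' generated stores are byte-reproducible under a seed.
#' @noRd
now_utc <- function(coll = NULL) {
  if (!is.null(coll) && !is.null(coll$fixed_time)) return(coll$fixed_time)
  format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

next_id <- function(coll, prefix) {
  coll$counter <- coll$counter + 1L
  sprintf("%s-%06d", prefix, coll$counter)
}

# 0-based half-open slice of section text
slice_text <- function(text, start, end) substr(text, start + 1L, end)

escape_regex <- function(s) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", s)

# ---- identity keys (deduplication, consensus, agreement, diff) --------------

mention_key <- function(document_id, section, start, end) {
  paste(document_id, section, start, end, sep = .SEP)
}

mention_key_of <- function(m) mention_key(m$document_id, m$section, m$start, m$end)

link_keys_of <- function(m) {
  if (length(m$concepts) == 0L) return(character(0))
  paste(mention_key_of(m), sort(m$concepts), sep = .SEP)
}

# A component's key is its concept id, its mention span key, or its
# lower-cased trimmed free text (free text allowed on predicates only).
comp_key <- function(comp, set) {
  switch(comp$kind,
    concept = paste0("c", .SEP, comp$ref),
    text    = paste0("t", .SEP, tolower(trimws(comp$ref))),
    mention = {
      m <- set$mentions[[comp$ref]]
      if (is.null(m)) abort_domain("relationship references unknown mention '%s'", comp$ref)
      paste0("m", .SEP, mention_key_of(m))
    },
    abort_domain("unknown component kind '%s'", comp$kind)
  )
}

rel_key_of <- function(r, set) {
  paste(comp_key(r$subject, set), comp_key(r$predicate, set), comp_key(r$object, set),
        sep = .SEP)
}

rel_pair_key_of <- function(r, set) {
  paste(comp_key(r$subject, set), comp_key(r$object, set), sep = .SEP)
}

assertion_key_of <- function(a) paste(a$subject, a$predicate, a$object, sep = .SEP)

assertion_pair_key_of <- function(a) paste(a$subject, a$object, sep = .SEP)

label_key_of <- function(l) paste(l$document_id, l$label, sep = .SEP)

empty_set <- function() {
  list(mentions = list(), relationships = list(), assertions = list(), labels = list())
}

# canonical JSON for arbitrary (list) state; stable key order, no whitespace
canonical_json <- function(x) {
  x <- canonical_sort(x)
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, null = "null", digits = NA))
}

canonical_sort <- function(x) {
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm) && all(nzchar(nm))) x <- x[order(nm)]
    lapply(x, canonical_sort)
  } else x
}
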