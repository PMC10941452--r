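# Directory-per-collection file store: collection.json (metadata, labels,
# members, rounds), concepts.csv (registry), documents/*.json, and one
# annotation file per (round, annotator, document) under
# annotations/round-<r>/<annotator>/<document>.json.

#' Save a collection to a directory
#'
#' @param coll A collection.
#' @param dir Target directory (created if missing; one directory per
#'   collection).
#' @export
save_collection <- function(coll, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(collection_id = coll$collection_id, name = coll$name,
               description = coll$description, creator = coll$creator,
               members = as.list(coll$members), labels = as.list(coll$labels),
               rounds = lapply(coll$rounds, function(r)
                 list(round_index = r$round_index, members = as.list(r$members),
                      source_round = r$source_round)),
               counter = coll$counter, fixed_time = coll$fixed_time)
  writeLines(as.character(jsonlite::toJSON(meta, auto_unbox = TRUE,
                                           null = "null", pretty = TRUE)),
             file.path(dir, "collection.json"))
  utils::write.csv(coll$registry, file.path(dir, "concepts.csv"),
                   row.names = FALSE)
  docdir <- file.path(dir, "documents")
  dir.create(docdir, showWarnings = FALSE)
  for (doc in coll$documents) {
    payload <- list(document_id = doc$document_id,
                    sections = as.list(doc$sections),
                    metadata = doc$metadata)
    writeLines(as.character(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                             null = "null", pretty = TRUE)),
               file.path(docdir, paste0(doc$document_id, ".json")))
  }
  for (r in seq_along(coll$ann)) {
    for (annotator in names(coll$ann[[r]])) {
      for (doc_id in names(coll$ann[[r]][[annotator]])) {
        adir <- file.path(dir, "annotations", sprintf("round-%d", r), annotator)
        dir.create(adir, showWarnings = FALSE, recursive = TRUE)
        set <- coll$ann[[r]][[annotator]][[doc_id]]
        writeLines(as.character(jsonlite::toJSON(set, auto_unbox = TRUE,
                                                 null = "null", pretty = TRUE)),
                   file.path(adir, paste0(doc_id, ".json")))
      }
    }
  }
  invisible(dir)
}

#' Load a collection from a directory
#'
#' Re-validates every mention's span/surface consistency against the
#' document text on load.
#'
#' @param dir Directory written by [save_collection()].
#' @return A collection.
#' @export
load_collection <- function(dir) {
  meta <- jsonlite::fromJSON(read_utf8(file.path(dir, "collection.json")),
                             simplifyVector = FALSE)
  coll <- create_collection(meta$name, meta$description, meta$creator,
                            collection_id = meta$collection_id,
                            members = unlist(meta$members),
                            labels = unlist(meta$labels) %||% character(0))
  coll$rounds <- lapply(meta$rounds, function(r)
    list(round_index = as.integer(r$round_index),
         members = unlist(r$members), source_round = r$source_round))
  coll$counter <- as.integer(meta$counter)
  coll$fixed_time <- meta$fixed_time
  reg_path <- file.path(dir, "concepts.csv")
  if (file.exists(reg_path)) {
    reg <- utils::read.csv(reg_path, colClasses = "character")
    if (nrow(reg) > 0L) register_concepts(coll, reg)
  }
  for (f in sort(list.files(file.path(dir, "documents"), pattern = "\\.json$",
                            full.names = TRUE))) {
    rec <- jsonlite::fromJSON(read_utf8(f), simplifyVector = FALSE)
    add_document(coll, new_document(rec$document_id,
                                    unlist(rec$sections),
                                    metadata = rec$metadata))
  }
  coll$ann <- rep(list(list()), length(coll$rounds))
  anndir <- file.path(dir, "annotations")
  fix_names <- function(lst) {
    names(lst) <- vapply(lst, function(x) x$id, character(1))
    lst
  }
  if (dir.exists(anndir)) {
    for (rdir in sort(list.dirs(anndir, recursive = FALSE))) {
      r <- as.integer(sub("^round-", "", basename(rdir)))
      for (adir in sort(list.dirs(rdir, recursive = FALSE))) {
        annotator <- basename(adir)
        for (f in sort(list.files(adir, pattern = "\\.json$", full.names = TRUE))) {
          doc_id <- tools::file_path_sans_ext(basename(f))
          raw <- jsonlite::fromJSON(read_utf8(f), simplifyVector = FALSE)
          set <- empty_set()
          for (m in raw$mentions) {
            m$concepts <- as.character(unlist(m$concepts))
            m$start <- as.integer(m$start); m$end <- as.integer(m$end)
            text <- section_text(coll, doc_id, m$section)
            if (!identical(slice_text(text, m$start, m$end), m$surface))
              abort_domain("mention %s in %s: surface does not match text slice",
                           m$id, f)
            set$mentions[[m$id]] <- m
          }
          for (r2 in raw$relationships) set$relationships[[r2$id]] <- r2
          for (a in raw$assertions) set$assertions[[a$id]] <- a
          for (l in raw$labels) set$labels[[l$id]] <- l
          coll$ann[[r]][[annotator]][[doc_id]] <- set
        }
      }
    }
  }
  coll
}
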