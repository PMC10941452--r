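test_that("plain-text ingestion is lossless, one section per file", {
  f <- tempfile(fileext = ".txt")
  writeLines("abc", f, sep = "")
  doc <- read_txt_document(f)
  expect_equal(doc$document_id, tools::file_path_sans_ext(basename(f)))
  expect_equal(unname(doc$sections[["text"]]), "abc")
  # trailing newline preserved: no silent normalization, offsets stay valid
  writeLines("abc\n", f, sep = "")
  expect_equal(unname(read_txt_document(f)$sections[["text"]]), "abc\n")
  writeLines("", f, sep = "")
  expect_error(read_txt_document(f), "empty")
})

test_that("CSV ingestion maps rows to documents and headers to sections", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("id,title,abstract", "d1,T1,A1", "d2,T2,"), f)
  docs <- read_csv_documents(f)
  expect_length(docs, 2)
  expect_equal(names(docs[[1]]$sections), c("title", "abstract"))
  expect_equal(unname(docs[[1]]$sections[["abstract"]]), "A1")
  # empty cell yields a present-but-empty section
  expect_equal(unname(docs[[2]]$sections[["abstract"]]), "")
  writeLines(c("id,title", "d1,T1", "d1,T2"), f)
  expect_error(read_csv_documents(f), "d1")
  # without an id column, the first column is used with a warning
  writeLines(c("pmid,abstract", "p1,A1"), f)
  expect_warning(docs <- read_csv_documents(f), "first column")
  expect_equal(docs[[1]]$document_id, "p1")
})

test_that("JSON ingestion accepts flat records only", {
  f <- tempfile(fileext = ".json")
  writeLines('[{"id":"d1","abstract":"Some text"}]', f)
  docs <- read_json_documents(f)
  expect_length(docs, 1)
  expect_equal(names(docs[[1]]$sections), "abstract")
  writeLines('[{"abstract":"No id here"}]', f)
  expect_equal(read_json_documents(f)[[1]]$document_id, "doc-000001")
  writeLines('[{"id":"d1","nested":{"a":1}}]', f)
  expect_error(read_json_documents(f), "flat records")
})

test_that("concept templates validate mandatory fields with row numbers", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("identifier,name,type,description",
               "MESH:D001943,Breast Neoplasms,Disease,"), f)
  df <- load_concepts(f)
  expect_equal(df$identifier, "MESH:D001943")
  expect_equal(df$description, "")
  writeLines(c("identifier,name,type", "MESH:1,Thing,Disease", "MESH:2,Other,"),
             f)
  expect_error(load_concepts(f), "row 2: type mandatory")
  writeLines(c("identifier,name,type", "X:1,A,T", "X:1,B,T"), f)
  expect_error(load_concepts(f), "conflicting")
  # identical duplicates collapse
  writeLines(c("identifier,name,type", "X:1,A,T", "X:1,A,T"), f)
  expect_equal(nrow(load_concepts(f)), 1)
  fj <- tempfile(fileext = ".json")
  writeLines('[{"uri":"GO:1","name":"N","type":"Process"}]', fj)
  expect_equal(load_concepts(fj)$identifier, "GO:1")
})

test_that("bibliographic fetch maps stub records to documents", {
  fetcher <- stub_fetcher(list(
    "27839516" = list(title = "T", abstract = "A", authors = list("X"),
                      venue = "V", publication_date = "2016-11-14"),
    "10.1/xyz" = list(title = "OnlyTitle", abstract = "")))
  doc <- fetch_record("27839516", "pubmed", fetcher)
  expect_equal(doc$document_id, "pubmed_27839516")
  expect_equal(names(doc$sections), c("title", "abstract"))
  expect_equal(doc$metadata$id_kind, "pmid")
  # identifier/source mismatch
  expect_error(fetch_record("10.1/xyz", "pubmed", fetcher), "requires a PMID")
  expect_error(fetch_record("27839516", "openaire", fetcher), "requires a DOI")
  # empty abstract: the section is omitted
  doc2 <- fetch_record("10.1/xyz", "semanticscholar", fetcher)
  expect_equal(names(doc2$sections), "title")
  # fetcher failure surfaces with the source name
  expect_error(fetch_record("999", "pubmed", fetcher), "pubmed")
})

test_that("ingested documents satisfy the document invariants", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("id,title,abstract", "d1,Some title,Some abstract text"), f)
  coll <- create_collection("c", "ingest target", "boss")
  for (d in read_csv_documents(f)) add_document(coll, d)
  expect_equal(unname(section_text(coll, "d1", "title")), "Some title")
})
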