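golden_prompts <- function() {
  jsonlite::read_json(test_path("golden", "prompts.json"),
                      simplifyVector = TRUE)
}

test_that("assembled prompts are byte-identical to the golden texts", {
  g <- golden_prompts()
  rec <- patent_record("US-1", title = "T", abstract = "A",
                       description = "D")
  p <- build_summarization_prompt(rec)
  expect_identical(p$system, g$summarization_system)
  expect_identical(substr(p$user, 1, nchar(g$summarization_user)),
                   g$summarization_user)
  expect_identical(p$temperature, 0)
  # the record is appended after the fixed instruction
  expect_identical(substring(p$user, nchar(g$summarization_user) + 1),
                   "\n\nTitle: T\nAbstract: A\nDescription: D")

  ps <- build_similarity_prompt(c("antiviral"), c("protease inhibitor"))
  expect_identical(ps$system, g$similarity_system)
  expect_identical(substr(ps$user, 1, nchar(g$similarity_user)),
                   g$similarity_user)

  # an empty description still yields a well-formed prompt
  p0 <- build_summarization_prompt(patent_record("US-2"))
  expect_true(startsWith(p0$user, substr(g$summarization_user, 1, 40)))
})

test_that("descriptions are capped at the configured character limit", {
  long <- strrep("x", 4000L)
  rec <- patent_record("US-9", description = long)
  expect_identical(nchar(rec$description), 3500L)
  expect_true(rec$truncated)
  rec2 <- patent_record("US-9", description = "short")
  expect_false(rec2$truncated)
  p <- build_summarization_prompt(rec)
  expect_false(grepl(strrep("x", 3501L), p$user, fixed = TRUE))
})

test_that("patent sampling is capped, seeded, and uniform", {
  ids <- sprintf("US-%02d", 1:5)
  expect_identical(sample_patents(ids, limit = 10L), ids)
  many <- sprintf("US-%02d", 1:30)
  s1 <- sample_patents(many, limit = 10L, seed = 5L)
  s2 <- sample_patents(many, limit = 10L, seed = 5L)
  expect_identical(s1, s2)
  expect_length(s1, 10L)
  expect_false(any(duplicated(s1)))
  # Monte Carlo: each id selected with probability 1/3 across seeds
  n_rep <- 600L
  counts <- table(factor(unlist(lapply(seq_len(n_rep), function(s) {
    sample_patents(many, limit = 10L, seed = s)
  })), levels = many))
  p <- 1 / 3
  sigma <- sqrt(n_rep * p * (1 - p))
  expect_true(all(abs(counts - n_rep * p) <= 3 * sigma))
})

test_that("label responses parse by the declared syntax", {
  r <- parse_label_response("antiviral/protease inhibitor/peptidase inhibitor")
  expect_identical(r$labels,
                   c("antiviral", "protease inhibitor", "peptidase inhibitor"))
  expect_true(r$parse_ok)
  expect_identical(parse_label_response("NA")$labels, character(0))
  expect_true(parse_label_response("NA")$parse_ok)
  expect_identical(parse_label_response(" Antiviral /NA")$labels, "antiviral")
  bad <- parse_label_response("here are some words but no separators at all")
  expect_false(bad$parse_ok)
  expect_identical(bad$labels, character(0))
  # short unseparated answers still count as a single label
  one <- parse_label_response("antiviral")
  expect_true(one$parse_ok)
  expect_identical(one$labels, "antiviral")
})

test_that("similarity verdicts parse only the yes/no --- explanation form", {
  v <- parse_similarity_verdict("yes --- both are serotonergic ligands")
  expect_true(v$verdict)
  expect_identical(v$explanation, "both are serotonergic ligands")
  expect_true(v$parse_ok)
  v2 <- parse_similarity_verdict("No --- unrelated targets")
  expect_false(v2$verdict)
  expect_false(parse_similarity_verdict("maybe --- unclear")$parse_ok)
  expect_false(parse_similarity_verdict("yes, definitely")$parse_ok)
})

test_that("the offline labeling pipeline aggregates per-molecule label sets", {
  resolver <- function(pid) {
    patent_record(pid, title = paste("Antiviral compositions", pid),
                  abstract = "a", description = "d")
  }
  mols <- list(m1 = sprintf("P%02d", 1:4), m2 = sprintf("Q%02d", 1:15))
  prompts <- unlist(lapply(names(mols), function(m) {
    lapply(sample_patents(mols[[m]], 10L, seed = 2L), function(pid) {
      build_summarization_prompt(resolver(pid))
    })
  }), recursive = FALSE)

  for (behavior in c("faithful", "malformed", "na")) {
    tr <- make_llm_transcript(prompts, behavior = behavior)
    llm <- transcript_llm(tr)
    ls1 <- label_molecule("CCO", mols$m1, resolver, llm, seed = 2L)
    expect_s3_class(ls1, "patent_label_set")
    oks <- vapply(ls1$provenance, function(p) p$parse_ok, logical(1))
    if (behavior == "faithful") {
      expect_true(all(oks))
      expect_gt(length(ls1$labels), 0L)
      expect_identical(ls1$labels, unique(tolower(ls1$labels)))
    } else if (behavior == "malformed") {
      expect_true(all(!oks))          # flagged, but the pipeline completed
      expect_identical(ls1$labels, character(0))
    } else {
      expect_true(all(oks))           # NA is valid syntax
      expect_identical(ls1$labels, character(0))
    }
    # the 10-patent cap holds
    ls2 <- label_molecule("CCN", mols$m2, resolver, llm, seed = 2L)
    expect_lte(length(ls2$provenance), 10L)
  }
})

test_that("functional verdicts follow shared labels on canned transcripts", {
  q <- c("antiviral", "protease inhibitor")
  shared <- c("antiviral", "kinase inhibitor")
  disjoint <- c("dye", "pigment")
  prompts <- list(build_similarity_prompt(q, shared),
                  build_similarity_prompt(q, disjoint),
                  build_similarity_prompt(q, q))
  llm <- transcript_llm(make_llm_transcript(prompts, "faithful"))
  expect_true(functional_verdict(q, shared, llm)$verdict)
  expect_false(functional_verdict(q, disjoint, llm)$verdict)
  expect_true(functional_verdict(q, q, llm)$verdict)  # identical sets agree
  bad_llm <- transcript_llm(make_llm_transcript(prompts, "malformed"))
  v <- functional_verdict(q, shared, bad_llm)
  expect_false(v$parse_ok)
  expect_true(is.na(v$verdict))
})

test_that("validation metrics reproduce confusion-matrix arithmetic", {
  perfect <- validation_metrics(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE))
  expect_equal(perfect$accuracy, 1.0)
  expect_equal(perfect$precision, 1.0)
  expect_equal(perfect$recall, 1.0)

  pred <- c(rep(TRUE, 48), rep(TRUE, 3), rep(FALSE, 2), rep(FALSE, 47))
  gold <- c(rep(TRUE, 48), rep(FALSE, 3), rep(TRUE, 2), rep(FALSE, 47))
  m <- validation_metrics(pred, gold)
  expect_equal(m$accuracy, 0.95, tolerance = 1e-12)
  expect_equal(m$precision, 48 / 51, tolerance = 1e-12)
  expect_equal(m$recall, 0.96, tolerance = 1e-12)
  expect_identical(unname(m$confusion), c(48L, 3L, 2L, 47L))

  none <- validation_metrics(rep(FALSE, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(none$recall, 0)
  expect_equal(none$precision, 0)
  expect_false(none$precision_defined)
})

test_that("transcripts round-trip through JSON lines", {
  prompts <- list(build_similarity_prompt("a", "b"))
  tr <- make_llm_transcript(prompts, "faithful")
  path <- tempfile(fileext = ".jsonl")
  write_transcript(tr, path)
  tr2 <- read_transcript(path)
  expect_identical(tr2$key, tr$key)
  expect_identical(tr2$response, tr$response)
  expect_error(transcript_llm(tr)("other system", "other user"),
               "no canned response")
})
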