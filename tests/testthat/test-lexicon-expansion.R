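test_that("tokenizer lowercases, strips punctuation and keeps dotted abbreviations", {
  expect_identical(tokenize(""), character(0))
  expect_identical(tokenize("Pt CLAIMS he had fever."),
                   c("pt", "claims", "he", "had", "fever"))
  toks <- tokenize("pt has D.M. and H.F.")
  expect_true(all(c("d.m.", "h.f.") %in% toks))
  expect_identical(tokenize("…claims smoking"), c("claims", "smoking"))
})

make_distributional_corpus <- function(seed, variant = "claimes", base = "claims",
                                       n_base = 400, n_variant = 150) {
  set.seed(seed)
  ctx <- c("pt %s fever today", "pt %s pain in the knee",
           "patient %s dizziness this morning", "pt %s chest pain at rest")
  verbs <- sample(c(rep(base, n_base), rep(variant, n_variant)))
  filler_words <- c("wound", "dressing", "bp", "log", "plan", "visit",
                    "edema", "gait", "stairs", "meds", "diet", "aide")
  filler <- replicate(500, paste(sample(filler_words, 6, TRUE), collapse = " "))
  tokenize_corpus(c(sprintf(sample(ctx, length(verbs), TRUE), verbs), filler))
}

test_that("embedding contracts: dimension, min_count threshold, empty corpus", {
  tc <- make_distributional_corpus(1)
  mod <- train_embeddings(tc, dim = 40, window = 5, min_count = 5)
  expect_equal(ncol(mod$vectors), 40L)
  expect_true(all(mod$vocab_counts >= 5))
  # a token occurring min_count - 1 times is absent
  rare <- paste(rep("zyzzyva", 4), collapse = " ")
  tc2 <- tokenize_corpus(c(rep("pt doing well today", 30), rep(rare, 1)))
  mod2 <- train_embeddings(tc2, dim = 10, min_count = 5)
  expect_false("zyzzyva" %in% rownames(mod2$vectors))
  expect_error(train_embeddings(tokenize_corpus(character()), dim = 10), "empty")
})

test_that("tokens planted in shared contexts become distributional neighbors", {
  tc <- make_distributional_corpus(2, variant = "admits")
  mod <- train_embeddings(tc, dim = 50, min_count = 5)
  vecs <- mod$vectors
  sim <- function(a, b) {
    va <- vecs[a, ]; vb <- vecs[b, ]
    sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
  }
  set.seed(3)
  pairs <- replicate(200, sample(rownames(vecs), 2))
  random_sims <- apply(pairs, 2, function(p) sim(p[1], p[2]))
  expect_gt(sim("claims", "admits"), stats::median(random_sims))
})

test_that("neighbor queries obey k, exclude the query, and reject OOV terms", {
  tc <- make_distributional_corpus(4)
  mod <- train_embeddings(tc, dim = 50, min_count = 5)
  expect_equal(nrow(query_neighbors(mod, "claims", 0)), 0L)
  nb <- query_neighbors(mod, "claims", 10)
  expect_false("claims" %in% nb$token)
  expect_true(all(diff(nb$similarity) <= 1e-12))
  expect_true("claimes" %in% nb$token)  # planted context-identical misspelling
  expect_error(query_neighbors(mod, "zzzz", 5), "zzzz")
})

test_that("planted variants of each seed are recovered in the top 10 across replicates", {
  hits <- vapply(1:10, function(s) {
    tc <- make_distributional_corpus(100 + s)
    mod <- train_embeddings(tc, dim = 50, min_count = 5)
    "claimes" %in% query_neighbors(mod, "claims", 10)$token
  }, NA)
  expect_gte(sum(hits), 8L)
})

test_that("neighbor ranking is invariant under vector rescaling", {
  tc <- make_distributional_corpus(5)
  mod <- train_embeddings(tc, dim = 30, min_count = 5)
  scaled <- mod
  scaled$vectors <- mod$vectors * 7.5
  expect_identical(query_neighbors(mod, "claims", 15)$token,
                   query_neighbors(scaled, "claims", 15)$token)
})

test_that("lexicon expansion merges accepts, rejects, and flags conflicts", {
  seeds <- default_seeds()
  expect_identical(sort(lexicon_canonicals(expand_lexicon(seeds))), sort(seeds))

  dec <- tibble::tibble(
    candidate = c("admits", "claimes", "clamed", "believes"),
    canonical = c("admits", "claims", "claims", "believes"),
    decision = c("accept", "accept", "reject", "accept")
  )
  lex <- expand_lexicon(seeds, dec)
  expect_true("admits" %in% lexicon_canonicals(lex))
  expect_true("claimes" %in% lex$variants$claims)
  expect_false("clamed" %in% unlist(lex$variants))

  conflict <- rbind(dec, tibble::tibble(candidate = "claimes", canonical = "states",
                                        decision = "accept"))
  expect_error(expand_lexicon(seeds, conflict), "more than one canonical")
})

test_that("expansion is monotone in accepted candidates", {
  seeds <- default_seeds()
  dec1 <- tibble::tibble(candidate = "claimes", canonical = "claims", decision = "accept")
  dec2 <- rbind(dec1, tibble::tibble(candidate = "admits", canonical = "admits",
                                     decision = "accept"))
  s1 <- lexicon_surfaces(expand_lexicon(seeds, dec1))$surface
  s2 <- lexicon_surfaces(expand_lexicon(seeds, dec2))$surface
  expect_true(all(s1 %in% s2))
})

test_that("two reviewers' decisions merge; contradictions are flagged, not resolved", {
  a <- tibble::tibble(candidate = c("claimes", "admits"),
                      canonical = c("claims", "admits"),
                      decision = c("accept", "accept"))
  b <- tibble::tibble(candidate = c("claimes", "insisted"),
                      canonical = c("claims", "insists"),
                      decision = c("reject", "accept"))
  m <- merge_decisions(a, b)
  expect_setequal(m$decisions$candidate, c("admits", "insisted"))
  expect_true(all(m$conflicts$candidate == "claimes"))
  expect_setequal(m$conflicts$decision, c("accept", "reject"))
})

test_that("lexicon JSON round-trips, preserves split-token forms, versions the schema", {
  lex <- default_lexicon()
  path <- withr::local_tempfile(fileext = ".json")
  save_lexicon(lex, path)
  back <- load_lexicon(path)
  expect_equal(back, lex)
  expect_true("clai med" %in% back$variants$claims)

  expect_error(load_lexicon(withr::local_tempfile(fileext = ".json")), "not found")

  bad <- jsonlite::fromJSON(readLines(path), simplifyVector = TRUE)
  bad$version <- "9.0"
  path2 <- withr::local_tempfile(fileext = ".json")
  writeLines(as.character(jsonlite::toJSON(bad, auto_unbox = TRUE)), path2)
  expect_error(load_lexicon(path2), "schema mismatch")
})
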