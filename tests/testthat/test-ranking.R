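test_that("crop bounding rules match the stated arithmetic", {
  img <- matrix(0L, 30, 30)
  full <- matrix(TRUE, 30, 30)
  cr <- crop_for_embedding(img, full, 0.25)
  expect_identical(dim(cr$pixels), c(30L, 30L))     # full frame stays full
  small <- matrix(FALSE, 30, 30); small[5:6, 9:10] <- TRUE
  cr0 <- crop_for_embedding(img, small, 0)
  expect_identical(dim(cr0$pixels), c(2L, 2L))
  expect_identical(cr0$offset, c(5L, 9L))
  mid <- matrix(FALSE, 30, 30); mid[11:20, 11:20] <- TRUE
  cr25 <- crop_for_embedding(img, mid, 0.25)        # 10 px box + 2.5 px sides
  expect_identical(dim(cr25$pixels), c(15L, 15L))
  expect_error(crop_for_embedding(img, matrix(FALSE, 30, 30)), "empty")
})

test_that("semantic score is positive-mean minus negative-mean cosine", {
  v <- c(1, 0, 0, 0); u <- c(0, 1, 0, 0)
  pos <- list(semantic_prompt("a", "positive"))
  expect_equal(semantic_score(v, pos, list(v)), 1.0)
  expect_equal(semantic_score(u, pos, list(v)), 0.0)
  both <- list(semantic_prompt("a", "positive"),
               semantic_prompt("b", "negative"))
  expect_equal(semantic_score(v, both, list(v, -v)), 2.0)
  expect_error(semantic_score(v, list(semantic_prompt("b", "negative")),
                              list(v)), "positive prompt")
})

test_that("geometric score is exact at its optimum and zero outside the mask", {
  # 10 x 12 block exactly centred on a 100 x 80 frame, area = 1.5% of frame
  m <- matrix(FALSE, 100, 80); m[46:55, 35:46] <- TRUE
  pt <- fazseg:::prompt_point(50, 40)
  expect_equal(geometric_score(m, pt), 1.0)
  expect_identical(geometric_score(m, fazseg:::prompt_point(1, 1)), 0)
})

test_that("centrality factor follows exp(-distance / quarter-diagonal)", {
  h <- 100; w <- 100; D <- sqrt(h^2 + w^2) / 4
  centred <- matrix(FALSE, h, w); centred[50:51, 50:51] <- TRUE
  shifted <- matrix(FALSE, h, w); shifted[80:81, 50:51] <- TRUE
  s1 <- geometric_score(centred, fazseg:::prompt_point(50, 50), c(h, w))
  s2 <- geometric_score(shifted, fazseg:::prompt_point(80, 50), c(h, w))
  expect_equal(s2 / s1, exp(-30 / D), tolerance = 1e-12)
})

test_that("selection reduces to the expected degenerate behaviours", {
  m1 <- matrix(FALSE, 20, 20); m1[9:12, 9:12] <- TRUE
  m2 <- matrix(FALSE, 20, 20); m2[1:4, 1:4] <- TRUE
  p1 <- mask_proposal(m1, 0.5); p2 <- mask_proposal(m2, 0.5)
  # single proposal: selected, semantic normalizes to 1
  one <- rank_and_select(list(p1), 0.3, 0.8)
  expect_identical(one$selected, 1L)
  expect_equal(one$table$semantic_norm, 1)
  # identical semantic and generator scores: the central mask wins on geometry
  pt1 <- fazseg:::prompt_point(10, 10); pt2 <- fazseg:::prompt_point(2, 2)
  geo <- c(geometric_score(m1, pt1), geometric_score(m2, pt2))
  sel <- rank_and_select(list(p1, p2), c(0.4, 0.4), geo)
  expect_identical(sel$selected, 1L)
  # degenerate weights (0, 0, 1): argmax generator score
  p3 <- mask_proposal(m2, 0.9)
  sel2 <- rank_and_select(list(p1, p3), c(0.9, 0.1), c(0.2, 0.1),
                          weights = c(sem = 0, geo = 0, gen = 1))
  expect_identical(sel2$selected, 2L)
  expect_error(rank_and_select(list(), numeric(0), numeric(0)),
               class = "faz_no_proposal")
  expect_error(rank_and_select(list(p1), 1, 1, weights = c(sem = 0.9,
                                                           geo = 0.2,
                                                           gen = -0.1)),
               "weights")
})

test_that("total score is nondecreasing in each component score", {
  set.seed(53)
  m <- matrix(TRUE, 4, 4)
  for (rep in 1:40) {
    k <- sample(2:6, 1)
    sem <- runif(k); geo <- runif(k); gen <- runif(k)
    props <- lapply(gen, function(g) mask_proposal(m, g))
    base <- rank_and_select(props, sem, geo)$table$total
    i <- sample(k, 1); bump <- runif(1, 0, 0.5)
    sem2 <- sem; sem2[i] <- sem2[i] + bump
    expect_gte(rank_and_select(props, sem2, geo)$table$total[i],
               base[i] - 1e-12)
    geo2 <- geo; geo2[i] <- geo2[i] + bump
    expect_gte(rank_and_select(props, sem, geo2)$table$total[i],
               base[i] - 1e-12)
  }
})

test_that("selection is invariant to proposal order up to the tie-break", {
  set.seed(59)
  m <- matrix(TRUE, 4, 4)
  for (rep in 1:20) {
    k <- 5
    sem <- runif(k); geo <- runif(k); gen <- runif(k)
    props <- lapply(gen, function(g) mask_proposal(m, g))
    sel <- rank_and_select(props, sem, geo)$selected
    perm <- sample(k)
    sel_p <- rank_and_select(props[perm], sem[perm], geo[perm])$selected
    expect_identical(perm[sel_p], sel)
  }
})

test_that("mock embedder is deterministic, unit-norm, and table-driven", {
  emb <- mock_embedding_backend()
  crop <- matrix(runif(64, 0, 255), 8, 8)
  v1 <- emb$embed_image(crop); v2 <- emb$embed_image(crop)
  expect_identical(v1, v2)
  expect_equal(sqrt(sum(v1^2)), 1, tolerance = 1e-9)
  for (p in default_prompts()) {
    tv <- emb$embed_text(p$text)
    expect_equal(sqrt(sum(tv^2)), 1, tolerance = 1e-9)
  }
  expect_error(emb$embed_text("unheard-of phrase"), "configuration error")
})

test_that("a dark-centred crop beats a bright crop on the FAZ phrase", {
  emb <- mock_embedding_backend()
  prompts <- default_prompts()
  tv <- lapply(prompts, function(p) emb$embed_text(p$text))
  dark <- matrix(150, 20, 20); dark[6:15, 6:15] <- 30
  bright <- matrix(200, 20, 20); bright[6:15, 6:15] <- 230
  s_dark <- semantic_score(emb$embed_image(dark), prompts, tv)
  s_bright <- semantic_score(emb$embed_image(bright), prompts, tv)
  expect_gt(s_dark, s_bright)
})

test_that("the selected proposal is usually the best-overlap proposal", {
  samples <- clean_cohort()
  results <- clean_results()
  hits <- vapply(seq_along(samples), function(i) {
    ious <- vapply(results[[i]]$proposals,
                   function(p) iou(p$mask, samples[[i]]$gt_mask), numeric(1))
    results[[i]]$selected_index == which.max(ious)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
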