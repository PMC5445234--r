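test_that("a well-formed database loads, round-trips through CSV and JSON, and tallies correctly", {
  db <- tiny_db()
  expect_s3_class(db, "food_db")
  rep <- validate_database(db)
  expect_equal(rep$n_items, 6)
  expect_equal(rep$n_tagged, 1)
  expect_equal(rep$n_linked, 1)
  expect_equal(rep$n_probed, 1)
  expect_equal(rep$n_image_sets, 3)
  expect_equal(rep$n_unit_portions, 3)
  expect_equal(rep$n_supplements, 6)
  expect_equal(rep$n_supplement_categories, 3)

  csv <- withr::local_tempfile(fileext = ".csv")
  write_food_db(db, csv)
  db2 <- load_food_db(csv,
    probes = sub("\\.csv$", "_probes.csv", csv),
    supplements = sub("\\.csv$", "_supplements.csv", csv),
    supplement_categories = sub("\\.csv$", "_supplement_categories.csv", csv)
  )
  expect_equal(validate_database(db2), rep)
  expect_equal(db2$foods$food_id, db$foods$food_id)
  expect_equal(db2$foods$energy, db$foods$energy)

  js <- withr::local_tempfile(fileext = ".json")
  write_food_db(db, js)
  db3 <- load_food_db(js)
  expect_equal(validate_database(db3), rep)
  expect_equal(db3$foods$linked_ids, db$foods$linked_ids)
  expect_equal(db3$probes$effects, db$probes$effects)
})

test_that("referential-integrity violations are reported with locators", {
  base <- tiny_db()$foods
  dup <- dplyr::bind_rows(base, base[1, ])
  expect_error(food_db(dup), "duplicate food_id 'f001'")

  ghost <- base
  ghost$linked_ids[[2]] <- c("f003", "ghost")
  expect_error(food_db(ghost), "dangling linked_id 'ghost'")

  badgrp <- base
  badgrp$food_group[1] <- "Astronaut food"
  expect_error(food_db(badgrp), "unknown food_group")

  badnut <- base
  badnut$plutonium <- 1
  expect_error(food_db(badnut), "unknown nutrient_id")

  noportion <- base
  noportion$portion_kind[3] <- "telepathy"
  expect_error(food_db(noportion), "missing portion_spec")

  badprobe <- base
  badprobe$probe_ids[[2]] <- "pr99"
  expect_error(food_db(badprobe, probes = tiny_db()$probes), "dangling probe_id 'pr99'")
})

test_that("validate_database counts equal an independent scan on generated databases", {
  for (seed in c(7, 19)) {
    db <- generate_food_database(80, seed = seed)
    rep <- validate_database(db)
    f <- db$foods
    expect_equal(rep$n_tagged, sum(vapply(f$tags, length, integer(1)) > 0))
    expect_equal(rep$n_linked, sum(vapply(f$linked_ids, length, integer(1)) > 0))
    expect_equal(rep$n_probed, sum(vapply(f$probe_ids, length, integer(1)) > 0))
    expect_equal(rep$n_image_sets + rep$n_unit_portions, nrow(f))
    expect_equal(rep$n_image_sets, sum(f$portion_kind == "image"))
  }
})

test_that("tag-assisted search retrieves aliases and ranks matches as specified", {
  db <- tiny_db()
  hit <- search_foods(db, "Houmus")
  expect_equal(hit$description, "Hummus")
  expect_equal(hit$match_rank, 4L)

  # exact description outranks prefix and substring matches
  res <- search_foods(db, "hummus")
  expect_equal(res$description[1], "Hummus")
  expect_equal(res$match_rank, c(1L, 2L)) # exact, then description-prefix match

  expect_error(search_foods(db, "   "), "invalid query")
})

test_that("search equals a brute-force substring scan over descriptions and tags", {
  db <- generate_food_database(60, seed = 11)
  f <- db$foods
  set.seed(42)
  pool <- c(
    substring(f$description, 1, 4), "item", "alias", "synthetic", "zzz-none",
    toupper(substring(f$description, 5, 9))
  )
  for (q in sample(pool, 100, replace = TRUE)) {
    if (!nzchar(trimws(q))) next
    got <- search_foods(db, q)$food_id
    ql <- tolower(q)
    oracle <- f$food_id[vapply(seq_len(nrow(f)), function(i) {
      grepl(ql, tolower(f$description[i]), fixed = TRUE) ||
        any(grepl(ql, tolower(f$tags[[i]]), fixed = TRUE))
    }, logical(1))]
    expect_setequal(got, oracle)
  }
})

test_that("portion responses resolve to anchors, midpoints and symmetric extrapolations", {
  spec <- list(kind = "image", anchors = c(100, 200, 300))
  pr <- function(i, rel) portion_response("image", image_index = i, relation = rel)
  expect_equal(resolve_portion_weight(spec, pr(2, "exactly")), 200)
  expect_equal(resolve_portion_weight(spec, pr(1, "greater_than")), 150)
  expect_equal(resolve_portion_weight(spec, pr(2, "less_than")), 150)
  expect_equal(resolve_portion_weight(spec, pr(3, "greater_than")), 350)
  expect_equal(resolve_portion_weight(spec, pr(1, "less_than")), 50)
  # floor kicks in when the lower gap exceeds half of w1
  squashed <- list(kind = "image", anchors = c(30, 80, 120))
  expect_equal(resolve_portion_weight(squashed, pr(1, "less_than")), 15)

  unit <- list(kind = "unit", unit_weight = 12)
  expect_equal(
    resolve_portion_weight(unit, portion_response("unit", unit_count = 3)), 36
  )
  expect_error(resolve_portion_weight(unit, pr(1, "exactly")), "kind mismatch")
  expect_error(
    resolve_portion_weight(spec, portion_response("unit", unit_count = 2)),
    "kind mismatch"
  )
  expect_error(portion_response("unit", unit_count = 0), "positive")
})

test_that("portion weights are monotone in relation and image index", {
  set.seed(5)
  for (rep in 1:50) {
    w <- sort(runif(3, 10, 500))
    if (any(diff(w) <= 0)) next
    spec <- list(kind = "image", anchors = w)
    pr <- function(i, rel) portion_response("image", image_index = i, relation = rel)
    exact <- vapply(1:3, function(i) resolve_portion_weight(spec, pr(i, "exactly")), numeric(1))
    expect_true(all(diff(exact) > 0))
    for (i in 1:3) {
      expect_lt(resolve_portion_weight(spec, pr(i, "less_than")), exact[i])
      expect_gt(resolve_portion_weight(spec, pr(i, "greater_than")), exact[i])
    }
    expect_gt(resolve_portion_weight(spec, pr(1, "less_than")), 0)
  }
})

test_that("generic supplement composition is the per-nutrient median with the even-count convention", {
  db <- tiny_db()
  expect_equal(generic_supplement_composition(db, "vitc")$vitamin_c, 80)
  expect_equal(generic_supplement_composition(db, "even")$vitamin_c, 75)
  expect_error(generic_supplement_composition(db, "nope"), "empty or unknown")

  # 7 random supplements against a sort-and-pick oracle, any member order
  set.seed(9)
  ids <- default_nutrient_schema()$nutrient_id
  sup <- tibble::tibble(
    supplement_id = paste0("r", 1:7), brand = "x", category_id = "cat"
  )
  for (nid in ids) sup[[nid]] <- round(runif(7, 0, 50), 1)
  got <- generic_supplement_composition(sup, "cat")
  for (nid in ids) {
    v <- sort(sup[[nid]])
    expect_equal(got[[nid]], v[4]) # odd count: middle of the sorted values
  }
  shuffled <- sup[sample(7), ]
  expect_equal(generic_supplement_composition(shuffled, "cat"), got)
})

test_that("linked options and probes return stored order, empties, and unknown-id errors", {
  db <- tiny_db()
  lk <- linked_options(db, "f002")
  expect_equal(lk$food_id, c("f003", "f004", "f005"))
  expect_equal(nrow(linked_options(db, "f001")), 0)
  expect_error(linked_options(db, "f999"), "unknown food_id")

  expect_equal(probes_for(db, "f001")$probe_id, "pr1")
  expect_equal(nrow(probes_for(db, "f002")), 0)
  expect_error(probes_for(db, "f999"), "unknown food_id")

  # lookup equals a brute-force filter on a generated database
  g <- generate_food_database(50, seed = 3)
  for (fid in sample(g$foods$food_id, 10)) {
    expect_equal(
      linked_options(g, fid)$food_id,
      g$foods$linked_ids[[match(fid, g$foods$food_id)]]
    )
  }
})
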