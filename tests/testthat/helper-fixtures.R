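# Hand-built six-item database used across the suite: one tagged item with a
# substitution probe, one item with linked foods, two unit-portion condiments,
# the substitution target, and a unit-portion cracker. All compositions are
# round numbers so expected intakes can be computed by hand.
tiny_db <- function() {
  soups <- "Soups, sauces, and miscellaneous foods"
  foods <- tibble::tibble(
    food_id = c("f001", "f002", "f003", "f004", "f005", "f006"),
    description = c(
      "Hummus", "Chips", "Salt", "Vinegar", "Hummus retail", "Cream cracker"
    ),
    food_group = c(
      soups, "Potatoes and potato dishes", soups, soups, soups,
      "Biscuits, cakes, and pastries"
    ),
    category = "misc",
    tags = list("Houmus", character(0), character(0), character(0), character(0), character(0)),
    linked_ids = list(
      character(0), c("f003", "f004", "f005"), character(0), character(0),
      character(0), character(0)
    ),
    probe_ids = list("pr1", character(0), character(0), character(0), character(0), character(0)),
    portion_kind = c("image", "image", "unit", "unit", "image", "unit"),
    w1 = c(40, 100, NA, NA, 40, NA),
    w2 = c(80, 200, NA, NA, 80, NA),
    w3 = c(120, 300, NA, NA, 120, NA),
    unit_weight = c(NA, NA, 1, 15, NA, 12),
    energy = c(200, 250, 0, 20, 300, 440),
    protein = c(8, 4, 0, 0, 10, 10),
    sodium = c(400, 200, 38000, 20, 600, 600)
  )
  probes <- tibble::tibble(
    probe_id = "pr1",
    prompt = "Homemade or retail?",
    options = list(c("homemade", "retail")),
    effects = list(list(
      homemade = list(kind = "tag", value = "homemade"),
      retail = list(kind = "substitute", value = "f005")
    ))
  )
  supplements <- tibble::tibble(
    supplement_id = c("s1", "s2", "s3", "s4", "s5", "s6"),
    brand = paste("brand", 1:6),
    category_id = c("vitc", "vitc", "vitc", "even", "even", "b12"),
    vitamin_c = c(50, 80, 100, 50, 100, 0),
    vitamin_b12 = c(0, 0, 0, 0, 0, 1)
  )
  food_db(foods, probes = probes, supplements = supplements)
}

# a fully resolved 2-meal session over tiny_db(), for intake tests
resolved_session <- function(db = tiny_db()) {
  s <- start_session("p01", "2016-03-01")
  s <- add_meal(s, "lunch", "13:00", "home")
  s <- add_food(s, 1, "f002", db)
  s <- set_portion(s, 1, 1, portion_response("image", image_index = 2, relation = "exactly"), db)
  s <- add_food(s, 1, "f003", db)
  s <- set_portion(s, 1, 2, portion_response("unit", unit_count = 2), db)
  s
}

# random legal session against a generated db, driven through the public API
random_session <- function(db, participant = "px", date = "2016-01-01") {
  n_meals <- sample(1:3, 1)
  s <- start_session(participant, date)
  for (m in seq_len(n_meals)) {
    s <- add_meal(s, paste0("meal", m), sprintf("%02d:%02d", sample(0:23, 1), sample(0:59, 1)))
  }
  foods <- db$foods
  for (k in seq_len(sample(2:6, 1))) {
    mi <- sample(n_meals, 1)
    i <- sample(nrow(foods), 1)
    s <- add_food(s, mi, foods$food_id[i], db)
    ei <- length(s$meals[[mi]]$food_entries)
    entry <- s$meals[[mi]]$food_entries[[ei]]
    for (pid in entry$pending_probes) {
      p <- db$probes[db$probes$probe_id == pid, ]
      s <- answer_probe(s, mi, ei, pid, sample(p$options[[1]], 1), db)
    }
    # the entry's food may have been substituted; portion must match its spec
    kind <- db$foods$portion_kind[match(s$meals[[mi]]$food_entries[[ei]]$food_id, db$foods$food_id)]
    resp <- if (kind == "image") {
      portion_response("image",
        image_index = sample(1:3, 1),
        relation = sample(c("less_than", "exactly", "greater_than"), 1)
      )
    } else {
      portion_response("unit", unit_count = sample(1:4, 1))
    }
    s <- set_portion(s, mi, ei, resp, db)
  }
  finalize_session(s, usual_intake_flag = "usual")
}

expect_session_equal <- function(a, b) {
  expect_equal(tidy(a), tidy(b))
  expect_identical(a$state, b$state)
  expect_identical(a$usual_intake_flag, b$usual_intake_flag)
  expect_identical(a$forgotten_foods_reviewed, b$forgotten_foods_reviewed)
  expect_equal(length(a$supplements), length(b$supplements))
}
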