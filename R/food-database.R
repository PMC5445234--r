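#' Build an in-memory food/supplement database
#'
#' Assembles and validates the structured database a recall session runs
#' against: food and drink items with per-100 g composition, food-group
#' membership, free-text search tags, probe questions, linked-food rules and a
#' portion specification (either a 3-image anchor set or a unit weight);
#' branded supplements with per-dose composition grouped into categories.
#'
#' Referential integrity is checked eagerly: duplicate ids, unknown nutrient
#' columns, unknown food groups, missing or double portion specifications, and
#' dangling linked/probe/category references are all reported together, each
#' with a row locator.
#'
#' @param foods Tibble with columns `food_id`, `description`, `food_group`,
#'   `category`, `tags`, `linked_ids`, `probe_ids` (list-columns or
#'   ";"-separated strings), `portion_kind` (`"image"` or `"unit"`),
#'   `w1`,`w2`,`w3` (image anchor weights, g), `unit_weight` (g), plus one
#'   numeric column per nutrient in `schema` (per 100 g; missing nutrient
#'   columns are filled with 0).
#' @param probes Optional tibble with `probe_id`, `prompt`, `options`
#'   (list-column or ";"-separated) and optionally `effect_kinds`,
#'   `effect_values` (aligned with options; kind `"tag"` annotates the entry,
#'   `"substitute"` swaps the food for the referenced `food_id`).
#' @param supplements Optional tibble with `supplement_id`, `brand`,
#'   `category_id` plus nutrient columns (per dose).
#' @param supplement_categories Optional tibble `category_id`, `name`;
#'   derived from `supplements` when absent.
#' @param schema Nutrient schema tibble, see [default_nutrient_schema()].
#' @param food_groups Character vector of allowed food-group names.
#'
#' @return An object of class `food_db`.
#' @export
food_db <- function(foods,
                    probes = NULL,
                    supplements = NULL,
                    supplement_categories = NULL,
                    schema = default_nutrient_schema(),
                    food_groups = default_food_groups()) {
  foods <- tibble::as_tibble(foods)
  ids <- nutrient_ids(schema)
  errs <- character(0)
  locate <- function(row, id, what) sprintf("row %d (food_id '%s'): %s", row, id, what)

  req <- c("food_id", "description", "food_group", "portion_kind")
  miss <- setdiff(req, names(foods))
  if (length(miss) > 0) {
    stop("food table is missing required columns: ", paste(miss, collapse = ", "))
  }
  if (!"category" %in% names(foods)) foods$category <- NA_character_

  for (col in c("tags", "linked_ids", "probe_ids")) {
    if (!col %in% names(foods)) {
      foods[[col]] <- replicate(nrow(foods), character(0), simplify = FALSE)
    } else if (!is.list(foods[[col]])) {
      foods[[col]] <- lapply(foods[[col]], split_semi)
    }
  }
  for (col in c("w1", "w2", "w3", "unit_weight")) {
    if (!col %in% names(foods)) foods[[col]] <- NA_real_
  }

  fixed <- c(
    "food_id", "description", "food_group", "category", "tags", "linked_ids",
    "probe_ids", "portion_kind", "w1", "w2", "w3", "unit_weight"
  )
  nut_cols <- setdiff(names(foods), fixed)
  unknown <- setdiff(nut_cols, ids)
  if (length(unknown) > 0) {
    errs <- c(errs, paste0("unknown nutrient_id column(s): ", paste(unknown, collapse = ", ")))
  }
  for (nid in setdiff(ids, nut_cols)) foods[[nid]] <- 0
  foods <- foods[, c(fixed, ids)]

  dup <- foods$food_id[duplicated(foods$food_id)]
  for (d in unique(dup)) {
    errs <- c(errs, sprintf(
      "duplicate food_id '%s' (rows %s)", d,
      paste(which(foods$food_id == d), collapse = ", ")
    ))
  }
  for (i in seq_len(nrow(foods))) {
    fid <- foods$food_id[i]
    if (is.na(foods$description[i]) || !nzchar(trimws(foods$description[i]))) {
      errs <- c(errs, locate(i, fid, "empty description"))
    }
    if (!foods$food_group[i] %in% food_groups) {
      errs <- c(errs, locate(i, fid, paste0("unknown food_group '", foods$food_group[i], "'")))
    }
    pk <- foods$portion_kind[i]
    if (identical(pk, "image")) {
      w <- c(foods$w1[i], foods$w2[i], foods$w3[i])
      if (anyNA(w) || !all(w > 0) || !all(diff(w) > 0)) {
        errs <- c(errs, locate(i, fid, "image portion requires 0 < w1 < w2 < w3"))
      }
    } else if (identical(pk, "unit")) {
      if (is.na(foods$unit_weight[i]) || foods$unit_weight[i] <= 0) {
        errs <- c(errs, locate(i, fid, "unit portion requires unit_weight > 0"))
      }
    } else {
      errs <- c(errs, locate(i, fid, "missing portion_spec (portion_kind must be 'image' or 'unit')"))
    }
    bad_linked <- setdiff(foods$linked_ids[[i]], foods$food_id)
    for (b in bad_linked) {
      errs <- c(errs, locate(i, fid, paste0("dangling linked_id '", b, "'")))
    }
    if (fid %in% foods$linked_ids[[i]]) {
      errs <- c(errs, locate(i, fid, "food lists itself as a linked option"))
    }
    for (nid in intersect(ids, names(foods))) {
      v <- foods[[nid]][i]
      if (is.na(v) || v < 0) {
        errs <- c(errs, locate(i, fid, paste0("nutrient '", nid, "' must be a non-negative number")))
      }
    }
  }

  probes <- normalize_probes(probes)
  if (nrow(probes) > 0) {
    for (j in seq_len(nrow(probes))) {
      if (length(probes$options[[j]]) < 2) {
        errs <- c(errs, sprintf("probe '%s': fewer than 2 options", probes$probe_id[j]))
      }
      eff <- probes$effects[[j]]
      for (e in eff) {
        if (identical(e$kind, "substitute") && !e$value %in% foods$food_id) {
          errs <- c(errs, sprintf(
            "probe '%s': substitution target '%s' not in database",
            probes$probe_id[j], e$value
          ))
        }
      }
    }
  }
  for (i in seq_len(nrow(foods))) {
    bad_probe <- setdiff(foods$probe_ids[[i]], probes$probe_id)
    for (b in bad_probe) {
      errs <- c(errs, locate(i, foods$food_id[i], paste0("dangling probe_id '", b, "'")))
    }
  }

  if (!is.null(supplements)) {
    supplements <- tibble::as_tibble(supplements)
    sup_fixed <- c("supplement_id", "brand", "category_id")
    miss <- setdiff(sup_fixed, names(supplements))
    if (length(miss) > 0) {
      errs <- c(errs, paste0("supplement table missing columns: ", paste(miss, collapse = ", ")))
    } else {
      sup_nut <- setdiff(names(supplements), sup_fixed)
      unknown <- setdiff(sup_nut, ids)
      if (length(unknown) > 0) {
        errs <- c(errs, paste0(
          "unknown nutrient_id column(s) in supplements: ",
          paste(unknown, collapse = ", ")
        ))
      }
      for (nid in setdiff(ids, sup_nut)) supplements[[nid]] <- 0
      supplements <- supplements[, c(sup_fixed, ids)]
      dup <- unique(supplements$supplement_id[duplicated(supplements$supplement_id)])
      for (d in dup) errs <- c(errs, sprintf("duplicate supplement_id '%s'", d))
    }
  } else {
    supplements <- tibble::tibble(
      supplement_id = character(0), brand = character(0), category_id = character(0)
    )
    for (nid in ids) supplements[[nid]] <- numeric(0)
  }
  if (is.null(supplement_categories)) {
    supplement_categories <- tibble::tibble(category_id = unique(supplements$category_id))
    supplement_categories$name <- supplement_categories$category_id
  } else {
    supplement_categories <- tibble::as_tibble(supplement_categories)
    if (!"name" %in% names(supplement_categories)) {
      supplement_categories$name <- supplement_categories$category_id
    }
  }
  bad_cat <- setdiff(supplements$category_id, supplement_categories$category_id)
  for (b in unique(bad_cat)) {
    errs <- c(errs, sprintf("supplement category '%s' not declared", b))
  }

  if (length(errs) > 0) {
    stop("food database failed validation:\n  - ", paste(errs, collapse = "\n  - "),
      call. = FALSE
    )
  }

  structure(
    list(
      foods = foods, probes = probes, supplements = supplements,
      supplement_categories = supplement_categories,
      schema = tibble::as_tibble(schema), food_groups = food_groups
    ),
    class = "food_db"
  )
}

normalize_probes <- function(probes) {
  if (is.null(probes)) {
    return(tibble::tibble(
      probe_id = character(0), prompt = character(0),
      options = list(), effects = list()
    ))
  }
  probes <- tibble::as_tibble(probes)
  if (!is.list(probes$options)) probes$options <- lapply(probes$options, split_semi)
  if (!"effects" %in% names(probes)) {
    kinds <- if ("effect_kinds" %in% names(probes)) {
      lapply(probes$effect_kinds, split_semi)
    } else {
      lapply(probes$options, function(o) rep("tag", length(o)))
    }
    vals <- if ("effect_values" %in% names(probes)) {
      lapply(probes$effect_values, split_semi)
    } else {
      probes$options
    }
    probes$effects <- purrr::pmap(
      list(probes$options, kinds, vals),
      function(opts, k, v) {
        if (length(k) == 0) k <- rep("tag", length(opts))
        if (length(v) == 0) v <- opts
        purrr::map2(k, v, ~ list(kind = .x, value = .y)) |> setNames(opts)
      }
    )
  }
  probes[, c("probe_id", "prompt", "options", "effects")]
}

#' @export
print.food_db <- function(x, ...) {
  cat(sprintf(
    "<food_db> %d foods, %d probes, %d supplements in %d categories; %d nutrients\n",
    nrow(x$foods), nrow(x$probes), nrow(x$supplements),
    nrow(x$supplement_categories), nrow(x$schema)
  ))
  invisible(x)
}

#' Tidy a food database into its item table
#'
#' @param x A `food_db`.
#' @param ... Unused.
#' @return The `foods` tibble.
#' @export
tidy.food_db <- function(x, ...) x$foods

#' Load a food/supplement database from disk
#'
#' Reads either a single JSON file holding the whole nested database, or a
#' foods CSV with optional companion probes and supplements CSVs. All weights
#' are grams; the energy column is kcal per 100 g.
#'
#' @param path Foods CSV or database JSON.
#' @param probes,supplements,supplement_categories Optional companion CSV
#'   paths (CSV route only).
#' @param schema,food_groups Passed to [food_db()].
#' @return A validated `food_db`.
#' @export
load_food_db <- function(path, probes = NULL, supplements = NULL,
                         supplement_categories = NULL,
                         schema = default_nutrient_schema(),
                         food_groups = default_food_groups()) {
  stopifnot(file.exists(path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    return(food_db_from_json(path))
  }
  read1 <- function(p) {
    if (is.null(p)) return(NULL)
    readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
  }
  food_db(
    foods = read1(path), probes = read1(probes), supplements = read1(supplements),
    supplement_categories = read1(supplement_categories),
    schema = schema, food_groups = food_groups
  )
}

#' Write a food database
#'
#' JSON (`.json` path) keeps the whole database in one nested file; CSV writes
#' the foods table in the flat interchange layout (list-columns ";"-joined),
#' with companion files `<stem>_probes.csv` / `<stem>_supplements.csv` when
#' those tables are non-empty.
#'
#' @param db A `food_db`.
#' @param path Output path (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_food_db <- function(db, path) {
  stopifnot(inherits(db, "food_db"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    foods <- db$foods
    foods$tags <- lapply(foods$tags, as.character)
    foods$linked_ids <- lapply(foods$linked_ids, as.character)
    foods$probe_ids <- lapply(foods$probe_ids, as.character)
    obj <- list(
      schema = db$schema, food_groups = db$food_groups, foods = foods,
      probes = db$probes, supplements = db$supplements,
      supplement_categories = db$supplement_categories
    )
    jsonlite::write_json(obj, path,
      dataframe = "rows", auto_unbox = TRUE, digits = NA, null = "null", pretty = FALSE
    )
    return(invisible(path))
  }
  foods <- db$foods
  foods$tags <- vapply(foods$tags, join_semi, character(1))
  foods$linked_ids <- vapply(foods$linked_ids, join_semi, character(1))
  foods$probe_ids <- vapply(foods$probe_ids, join_semi, character(1))
  readr::write_csv(foods, path, progress = FALSE)
  stem <- sub("\\.csv$", "", path, ignore.case = TRUE)
  if (nrow(db$probes) > 0) {
    pr <- tibble::tibble(
      probe_id = db$probes$probe_id,
      prompt = db$probes$prompt,
      options = vapply(db$probes$options, join_semi, character(1)),
      effect_kinds = vapply(db$probes$effects, function(e) {
        join_semi(vapply(e, function(z) z$kind, character(1)))
      }, character(1)),
      effect_values = vapply(db$probes$effects, function(e) {
        join_semi(vapply(e, function(z) z$value, character(1)))
      }, character(1))
    )
    readr::write_csv(pr, paste0(stem, "_probes.csv"), progress = FALSE)
  }
  if (nrow(db$supplements) > 0) {
    readr::write_csv(db$supplements, paste0(stem, "_supplements.csv"), progress = FALSE)
    readr::write_csv(db$supplement_categories, paste0(stem, "_supplement_categories.csv"),
      progress = FALSE
    )
  }
  invisible(path)
}

food_db_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows_to_tibble <- function(rows, list_cols = character(0)) {
    dplyr::bind_rows(lapply(rows, function(r) {
      for (col in list_cols) r[[col]] <- list(as.character(unlist(r[[col]])))
      r[vapply(r, is.null, logical(1))] <- NA
      tibble::as_tibble(r)
    }))
  }
  foods <- rows_to_tibble(obj$foods, c("tags", "linked_ids", "probe_ids"))
  probes <- NULL
  if (length(obj$probes) > 0) {
    probes <- tibble::tibble(
      probe_id = vapply(obj$probes, `[[`, "", "probe_id"),
      prompt = vapply(obj$probes, `[[`, "", "prompt"),
      options = lapply(obj$probes, function(p) as.character(unlist(p$options))),
      effects = lapply(obj$probes, function(p) {
        lapply(p$effects, function(e) list(kind = e$kind, value = e$value))
      })
    )
  }
  sup <- if (length(obj$supplements) > 0) rows_to_tibble(obj$supplements) else NULL
  cats <- if (length(obj$supplement_categories) > 0) {
    rows_to_tibble(obj$supplement_categories)
  } else {
    NULL
  }
  food_db(
    foods = foods, probes = probes, supplements = sup, supplement_categories = cats,
    schema = dplyr::bind_rows(lapply(obj$schema, tibble::as_tibble)),
    food_groups = as.character(unlist(obj$food_groups))
  )
}

#' Summarize database contents
#'
#' Pure tally over a loaded database: how many items carry search tags,
#' linked-food rules, probe questions, image anchor sets or unit portions,
#' plus supplement and category counts.
#'
#' @param db A `food_db`.
#' @return One-row tibble with columns `n_items`, `n_tagged`, `n_linked`,
#'   `n_probed`, `n_image_sets`, `n_unit_portions`, `n_supplements`,
#'   `n_supplement_categories`.
#' @export
validate_database <- function(db) {
  stopifnot(inherits(db, "food_db"))
  f <- db$foods
  tibble::tibble(
    n_items = nrow(f),
    n_tagged = sum(lengths(f$tags) > 0),
    n_linked = sum(lengths(f$linked_ids) > 0),
    n_probed = sum(lengths(f$probe_ids) > 0),
    n_image_sets = sum(f$portion_kind == "image"),
    n_unit_portions = sum(f$portion_kind == "unit"),
    n_supplements = nrow(db$supplements),
    n_supplement_categories = nrow(db$supplement_categories)
  )
}

#' Free-text food search with tag support
#'
#' Case-insensitive substring search over item descriptions and their search
#' tags (aliases, brand names, common misspellings), with diacritics folded to
#' ASCII, so e.g. a query "Houmus" retrieves an item described "Hummus" that
#' carries the tag. Ranking: exact description match, then description prefix,
#' then description substring, then tag-only matches; ties broken
#' alphabetically by description.
#'
#' @param db A `food_db`.
#' @param query Search text; must be non-empty after trimming.
#' @return Tibble of matching food rows in rank order, with a `match_rank`
#'   column (1 = exact ... 4 = tag-only).
#' @export
search_foods <- function(db, query) {
  stopifnot(inherits(db, "food_db"))
  q <- fold_text(trimws(query))
  if (is.na(q) || !nzchar(q)) stop("invalid query: empty after trimming")
  f <- db$foods
  desc <- fold_text(f$description)
  in_desc <- stringr::str_detect(stringr::fixed(desc), stringr::fixed(q))
  in_tags <- vapply(f$tags, function(tg) {
    length(tg) > 0 && any(stringr::str_detect(fold_text(tg), stringr::fixed(q)))
  }, logical(1))
  rank <- dplyr::case_when(
    desc == q ~ 1L,
    startsWith(desc, q) ~ 2L,
    in_desc ~ 3L,
    in_tags ~ 4L,
    .default = NA_integer_
  )
  out <- f[!is.na(rank), , drop = FALSE]
  out$match_rank <- rank[!is.na(rank)]
  out[order(out$match_rank, out$description), , drop = FALSE]
}

#' Construct a portion response
#'
#' Either an image response (which of the 3 anchor photographs, and whether
#' the consumed amount was less than, exactly, or greater than it) or a unit
#' response (how many units were consumed).
#'
#' @param kind `"image"` or `"unit"`.
#' @param image_index 1, 2 or 3 (image kind).
#' @param relation `"less_than"`, `"exactly"` or `"greater_than"` (image kind).
#' @param unit_count Positive number of units (unit kind).
#' @return A list of class `portion_response`.
#' @export
portion_response <- function(kind, image_index = NULL, relation = NULL, unit_count = NULL) {
  kind <- match.arg(kind, c("image", "unit"))
  if (kind == "image") {
    stopifnot(!is.null(image_index), !is.null(relation))
    if (!image_index %in% 1:3) stop("image_index must be 1, 2 or 3")
    relation <- match.arg(relation, c("less_than", "exactly", "greater_than"))
    resp <- list(kind = "image", image_index = as.integer(image_index), relation = relation)
  } else {
    stopifnot(!is.null(unit_count))
    if (!is.numeric(unit_count) || unit_count <= 0) stop("unit_count must be positive")
    resp <- list(kind = "unit", unit_count = as.numeric(unit_count))
  }
  structure(resp, class = "portion_response")
}

#' Resolve a portion response to grams
#'
#' For image anchor sets `(w1, w2, w3)` the consumed weight is the anchor
#' itself for "exactly this size", and the midpoint toward the neighbouring
#' anchor for "less than" / "greater than". Beyond the outermost anchors the
#' midpoint rule is extended symmetrically: above the largest image the weight
#' is `w3 + (w3 - w2)/2`; below the smallest it is `w1 - (w2 - w1)/2`, floored
#' at `w1/2` so the result stays positive. Unit portions multiply the unit
#' weight by the reported count.
#'
#' @param spec A list with `kind = "image"` and `anchors = c(w1, w2, w3)`
#'   (strictly increasing, all positive), or `kind = "unit"` and
#'   `unit_weight`.
#' @param response A [portion_response()].
#' @return Weight in grams (> 0).
#' @export
#' @examples
#' resolve_portion_weight(
#'   list(kind = "image", anchors = c(100, 200, 300)),
#'   portion_response("image", image_index = 1, relation = "greater_than")
#' ) # 150
resolve_portion_weight <- function(spec, response) {
  stopifnot(is.list(spec), !is.null(spec$kind))
  if (!identical(spec$kind, response$kind)) {
    stop(sprintf(
      "portion kind mismatch: spec is '%s' but response is '%s'",
      spec$kind, response$kind
    ))
  }
  if (spec$kind == "unit") {
    if (response$unit_count <= 0) stop("unit_count must be positive")
    return(spec$unit_weight * response$unit_count)
  }
  w <- spec$anchors
  stopifnot(length(w) == 3, all(w > 0), all(diff(w) > 0))
  i <- response$image_index
  switch(response$relation,
    exactly = w[i],
    greater_than = if (i < 3) (w[i] + w[i + 1]) / 2 else w[3] + (w[3] - w[2]) / 2,
    less_than = if (i > 1) (w[i - 1] + w[i]) / 2 else max(w[1] - (w[2] - w[1]) / 2, w[1] / 2)
  )
}

portion_spec_for <- function(db, food_id) {
  row <- db$foods[db$foods$food_id == food_id, , drop = FALSE]
  if (nrow(row) == 0) stop(sprintf("unknown food_id '%s'", food_id))
  if (row$portion_kind == "image") {
    list(kind = "image", anchors = c(row$w1, row$w2, row$w3))
  } else {
    list(kind = "unit", unit_weight = row$unit_weight)
  }
}

#' Generic (unbranded) supplement composition
#'
#' When a respondent knows the supplement category but not the brand, the
#' generic option carries the per-nutrient median composition over all
#' branded supplements in that category. A nutrient absent from a brand
#' counts as 0; with an even number of brands the median is the mean of the
#' two middle values.
#'
#' @param db A `food_db` (or a supplements tibble with nutrient columns).
#' @param category_id Category to summarize.
#' @return One-row tibble of per-dose nutrient medians.
#' @export
generic_supplement_composition <- function(db, category_id) {
  sup <- if (inherits(db, "food_db")) db$supplements else tibble::as_tibble(db)
  ids <- if (inherits(db, "food_db")) {
    nutrient_ids(db$schema)
  } else {
    setdiff(names(sup), c("supplement_id", "brand", "category_id"))
  }
  members <- sup[sup$category_id == category_id, , drop = FALSE]
  if (nrow(members) == 0) stop(sprintf("supplement category '%s' is empty or unknown", category_id))
  out <- tibble::as_tibble(lapply(
    setNames(ids, ids),
    function(nid) median(dplyr::coalesce(members[[nid]], 0))
  ))
  out
}

#' Linked-food options for a primary selection
#'
#' Foods commonly consumed with the selected item (e.g. milk with breakfast
#' cereal), returned in the configured order so a session can offer them for
#' one-tap acceptance.
#'
#' @param db A `food_db`.
#' @param food_id Primary selection.
#' @return Tibble of linked food rows in stored order (0 rows when none).
#' @export
linked_options <- function(db, food_id) {
  stopifnot(inherits(db, "food_db"))
  row <- db$foods[db$foods$food_id == food_id, , drop = FALSE]
  if (nrow(row) == 0) stop(sprintf("unknown food_id '%s'", food_id))
  ids <- row$linked_ids[[1]]
  db$foods[match(ids, db$foods$food_id), , drop = FALSE]
}

#' Probe questions attached to a food
#'
#' @param db A `food_db`.
#' @param food_id Food to look up.
#' @return Tibble of probe rows in stored order (0 rows when none).
#' @export
probes_for <- function(db, food_id) {
  stopifnot(inherits(db, "food_db"))
  row <- db$foods[db$foods$food_id == food_id, , drop = FALSE]
  if (nrow(row) == 0) stop(sprintf("unknown food_id '%s'", food_id))
  ids <- row$probe_ids[[1]]
  db$probes[match(ids, db$probes$probe_id), , drop = FALSE]
}
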