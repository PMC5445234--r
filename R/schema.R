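#' Default nutrient schema
#'
#' The registered set of nutrient identifiers a food database and every
#' downstream intake table must draw from, together with the unit each is
#' carried in. The default covers energy plus the 26 nutrients a validation
#' analysis of an Irish adult cohort typically reports: macronutrients in
#' grams, fat-soluble vitamins and folate in micrograms, and the remaining
#' vitamins and minerals in milligrams. Food composition is stored per 100 g;
#' supplement composition per dose.
#'
#' @return A tibble with columns `nutrient_id` and `unit` (kcal, g, ug or mg).
#' @export
#' @examples
#' default_nutrient_schema()
default_nutrient_schema <- function() {
  tibble::tribble(
    ~nutrient_id,          ~unit,
    "energy",              "kcal",
    "protein",             "g",
    "carbohydrate",        "g",
    "sugars",              "g",
    "starch",              "g",
    "fiber",               "g",
    "fat",                 "g",
    "saturated_fat",       "g",
    "monounsaturated_fat", "g",
    "polyunsaturated_fat", "g",
    "retinol",             "ug",
    "carotene",            "ug",
    "vitamin_d",           "ug",
    "vitamin_b12",         "ug",
    "folate",              "ug",
    "vitamin_e",           "mg",
    "riboflavin",          "mg",
    "niacin",              "mg",
    "vitamin_b6",          "mg",
    "vitamin_c",           "mg",
    "calcium",             "mg",
    "magnesium",           "mg",
    "iron",                "mg",
    "copper",              "mg",
    "zinc",                "mg",
    "potassium",           "mg",
    "sodium",              "mg"
  )
}

#' Default food-group list
#'
#' The 19 analysis food groups used when comparing mean daily food-group
#' intakes between two assessment methods. A finer group/category structure
#' may be carried as item metadata, but group totals are always reported
#' against this list (configurable).
#'
#' @return Character vector of 19 group names.
#' @export
default_food_groups <- function() {
  c(
    "Grains, rice, pasta, and savories",
    "Bread and rolls",
    "Breakfast cereals",
    "Biscuits, cakes, and pastries",
    "Milk and yogurt",
    "Creams, ice creams, and desserts",
    "Cheeses",
    "Butter, spreading fats, and oils",
    "Eggs and egg dishes",
    "Potatoes and potato dishes",
    "Veg and veg dishes",
    "Fruit and fruit dishes",
    "Fish and fish dishes",
    "Meat and meat products",
    "Alcoholic beverages",
    "Beverages other (sugar-sweetened)",
    "Sugars, confectionary, preserves, and savory snacks",
    "Soups, sauces, and miscellaneous foods",
    "Nuts, seeds, herbs, and spices"
  )
}

nutrient_ids <- function(schema) {
  if (is.data.frame(schema)) schema$nutrient_id else as.character(schema)
}
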