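#' FFQ schema: item definitions for the 32-week pregnancy questionnaire
#'
#' Builds the questionnaire schema: 43 food/food-group items on the
#' five-category weekly frequency scale (variable codes c200-c211, c215-c220,
#' c222-c246), plus the additional questions the derivation needs -- fat on
#' meat, diet soft drinks, bread slices, take-aways, bread/fat/milk types,
#' slices spread with fat, milk uses, sugar spoons and drink counts.
#'
#' @param version Text label stored on the schema (default "6", the syntax
#'   version whose recodes this package implements).
#' @return An object of class \code{ffq_schema}: a list with \code{items}
#'   (data frame: code, question_id, label, scale) and \code{version}.
#' @export
ffq_schema <- function(version = "6") {
  w <- function(code, qid, label) data.frame(
    code = code, question_id = qid, label = label, scale = "weekly5",
    stringsAsFactors = FALSE)
  o <- function(code, qid, label, scale) data.frame(
    code = code, question_id = qid, label = label, scale = scale,
    stringsAsFactors = FALSE)

  weekly <- rbind(
    w("c200", "c1a", "Sausages, burgers"),
    w("c201", "c1b", "Pies, pasties"),
    w("c202", "c1c", "Meat (beef, lamb, pork, ham, bacon)"),
    w("c203", "c1d", "Poultry"),
    w("c204", "c1e", "Liver, liver pate, kidney, heart"),
    w("c205", "c1f", "White fish"),
    w("c206", "c1g", "Other (oily) fish"),
    w("c207", "c1h", "Shellfish"),
    w("c208", "c1i", "Eggs, quiche"),
    w("c209", "c1j", "Cheese"),
    w("c210", "c1k", "Pizza"),
    w("c211", "c1l", "Chips"),
    w("c215", "c1m", "Roast potatoes"),
    w("c216", "c1n", "Boiled, mashed, jacket potatoes"),
    w("c217", "c1o", "Rice"),
    w("c218", "c1p", "Pasta"),
    w("c219", "c1q", "Crisps"),
    w("c220", "c1r", "Fried foods"),
    w("c222", "c3a", "Baked beans"),
    w("c223", "c3b", "Peas, sweetcorn, broad beans"),
    w("c224", "c3c", "Cabbage, sprouts and other green leafy vegetables"),
    w("c225", "c3d", "Other green vegetables"),
    w("c226", "c3e", "Carrots"),
    w("c227", "c3f", "Other root vegetables"),
    w("c228", "c3g", "Salad"),
    w("c229", "c3h", "Fresh fruit"),
    w("c230", "c3i", "Tinned juice"),
    w("c231", "c3j", "Pure juice not in tin"),
    w("c232", "c3k", "Pudding"),
    w("c233", "c3l", "Oat cereals"),
    w("c234", "c3m", "Wholegrain or bran cereals"),
    w("c235", "c3n", "Other cereals"),
    w("c236", "c3o", "Cakes or buns"),
    w("c237", "c3p", "Crispbreads"),
    w("c238", "c3q", "Biscuits"),
    w("c239", "c3r", "Chocolate bars"),
    w("c240", "c3s", "Pulses"),
    w("c241", "c3t", "Nuts, nut roast"),
    w("c242", "c3u", "Bean curd (tofu, miso)"),
    w("c243", "c3v", "Tahini"),
    w("c244", "c3w", "Soya 'meat', TVP, vegeburgers"),
    w("c245", "c3x", "Chocolate"),
    w("c246", "c3y", "Sweets")
  )

  extra <- rbind(
    o("c221", "c2",  "Do you eat all the fat on meat?", "categorical"),
    o("c247", "c4",  "How often do you choose low calorie or diet drinks?", "categorical"),
    o("c250", "c5",  "Pieces of bread, rolls or chapatis per day", "categorical"),
    o("c251", "c6",  "Take-away meals per month", "categorical"),
    o("c252", "c7a", "Bread type: white", "yesno"),
    o("c253", "c7b", "Bread type: brown or granary", "yesno"),
    o("c254", "c7c", "Bread type: wholemeal", "yesno"),
    o("c255", "c7d", "Bread type: chapattis or naan", "yesno"),
    o("c256", "c7e", "Doesn't usually eat bread", "yesno"),
    o("c260", "c8a_spread", "Spreading fat: butter, ghee, lard", "yesno"),
    o("c261", "c8b_spread", "Spreading fat: hard or soft margarine", "yesno"),
    o("c262", "c8c_spread", "Spreading fat: polyunsaturated spread", "yesno"),
    o("c263", "c8d_spread", "Spreading fat: low fat spread", "yesno"),
    o("c264", "c8e_spread", "Spreading fat: sunflower/soya/corn/olive oil", "yesno"),
    o("c265", "c8f_spread", "Spreading fat: other vegetable oil", "yesno"),
    o("c266", "c8a_fry", "Cooking fat: butter, ghee, lard", "yesno"),
    o("c267", "c8b_fry", "Cooking fat: hard or soft margarine", "yesno"),
    o("c268", "c8c_fry", "Cooking fat: polyunsaturated spread", "yesno"),
    o("c269", "c8d_fry", "Cooking fat: low fat spread", "yesno"),
    o("c270", "c8e_fry", "Cooking fat: sunflower/soya/corn/olive oil", "yesno"),
    o("c271", "c8f_fry", "Cooking fat: other vegetable oil", "yesno"),
    o("c275", "c9",   "Slices of bread spread with fat per day", "count"),
    o("c276", "c10a", "Milk type: full fat", "categorical"),
    o("c277", "c10b", "Milk type: semi-skimmed", "categorical"),
    o("c278", "c10c", "Milk type: skimmed", "categorical"),
    o("c279", "c10d", "Milk type: sterilised", "categorical"),
    o("c280", "c10e", "Milk type: dried milk", "categorical"),
    o("c281", "c10f", "Milk type: goat/sheep milk", "categorical"),
    o("c282", "c10g", "Milk type: soya milk", "categorical"),
    o("c283", "c10h", "Milk type: other", "categorical"),
    o("c284", "c11a", "Milk in tea", "categorical"),
    o("c285", "c11b", "Milk in coffee", "categorical"),
    o("c286", "c11c", "Milk on breakfast cereal", "categorical"),
    o("c287", "c11d", "Milk as pudding", "categorical"),
    o("c288", "c11e", "Milk to drink on its own", "categorical"),
    o("c289", "c11f", "Milk as a milky drink", "categorical"),
    o("c300", "c12a", "Cups of caffeinated tea per day", "count"),
    o("c301", "c12a2", "Cups of decaffeinated tea per day", "count"),
    o("c302", "c12b", "Spoons of sugar per cup of tea", "count"),
    o("c304", "c12d", "Cups of caffeinated coffee per day", "count"),
    o("c305", "c12d2", "Cups of decaffeinated coffee per day", "count"),
    o("c306", "c12e", "Spoons of sugar per cup of coffee", "count"),
    o("c310", "c13a", "Caffeinated cola drinks per day", "count"),
    o("c311", "c13b", "Decaffeinated cola drinks per day", "count")
  )

  items <- rbind(weekly, extra)
  stopifnot(!anyDuplicated(items$code), !anyDuplicated(items$question_id))
  structure(list(items = items, version = version), class = "ffq_schema")
}

#' Labels of the five-category weekly frequency scale
#'
#' @return Character vector of the five response options, in increasing
#'   frequency order (normalised form).
#' @export
weekly5_labels <- function() {
  c("never or rarely", "once in 2 weeks", "1-3 times a week",
    "4-7 times a week", "more than once a day")
}

#' Count items on the weekly five-category frequency scale
#'
#' @param schema An [ffq_schema()].
#' @return Integer count of weekly5-scale items (43 for the packaged schema).
#' @export
count_weekly_items <- function(schema) {
  stopifnot(inherits(schema, "ffq_schema"))
  sum(schema$items$scale == "weekly5")
}

#' @export
print.ffq_schema <- function(x, ...) {
  cat("FFQ schema (version ", x$version, "): ", nrow(x$items), " items, ",
      count_weekly_items(x), " on the weekly frequency scale\n", sep = "")
  invisible(x)
}

# codes of the weekly5 items, in schema order
weekly_codes <- function(schema) {
  schema$items$code[schema$items$scale == "weekly5"]
}

# question_id for a variable code (or NA)
question_for_code <- function(schema, code) {
  i <- match(code, schema$items$code)
  if (is.na(i)) NA_character_ else schema$items$question_id[i]
}
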