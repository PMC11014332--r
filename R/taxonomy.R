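#' Consolidation taxonomies
#'
#' Builds one of the three built-in taxonomies that consolidate the raw
#' annotation vocabulary into model classes:
#'
#' * `T1_sedentary` (posture channel): `sedentary` (sitting/reclining or lying
#'   down) vs `active` (every other posture or whole-body movement).
#' * `T2_activity_type` (posture channel): `sedentary` as in T1; `walking`
#'   ("walk", "walk with load"); `running`; `mixed_movement` for all other
#'   postures/whole-body movements.
#' * `T3_intensity` (intensity channel): the annotated MET-based intensity
#'   codes map 1:1 to `sedentary, light, moderate, vigorous`.
#'
#' @param name Taxonomy name.
#' @return A list of class `taxonomy_map` with elements `name`, `channel`,
#'   `classes` (ordered) and `rule` (named character vector, raw code ->
#'   class).
#' @export
#' @examples
#' tax <- taxonomy_map("T2_activity_type")
#' apply_taxonomy(c("biking", "walk"), tax)
taxonomy_map <- function(name = c("T1_sedentary", "T2_activity_type",
                                  "T3_intensity")) {
  name <- match.arg(name)
  post <- raw_vocabulary("posture")
  sed_codes <- c("sitting/reclining", "lying down")
  tax <- switch(name,
    T1_sedentary = list(
      channel = "posture",
      classes = c("sedentary", "active"),
      rule = setNames(ifelse(post %in% sed_codes, "sedentary", "active"), post)
    ),
    T2_activity_type = list(
      channel = "posture",
      classes = c("sedentary", "mixed_movement", "walking", "running"),
      rule = setNames(ifelse(post %in% sed_codes, "sedentary",
               ifelse(post %in% c("walk", "walk with load"), "walking",
               ifelse(post == "running", "running", "mixed_movement"))), post)
    ),
    T3_intensity = list(
      channel = "intensity",
      classes = c("sedentary", "light", "moderate", "vigorous"),
      rule = setNames(raw_vocabulary("intensity"), raw_vocabulary("intensity"))
    )
  )
  new_taxonomy_map(name, tax$channel, tax$classes, tax$rule)
}

new_taxonomy_map <- function(name, channel, classes, rule) {
  stopifnot(is.character(classes), length(classes) >= 2,
            channel %in% c("posture", "intensity"))
  if (!all(rule %in% classes)) {
    stop("taxonomy rule maps to unknown class(es): ",
         paste(setdiff(rule, classes), collapse = ", "))
  }
  vocab <- raw_vocabulary(channel)
  unmapped <- setdiff(vocab, names(rule))
  if (length(unmapped) > 0) {
    stop("taxonomy rule is not total; unmapped raw code(s): ",
         paste(unmapped, collapse = ", "))
  }
  structure(list(name = name, channel = channel, classes = classes,
                 rule = rule),
            class = "taxonomy_map")
}

#' @export
print.taxonomy_map <- function(x, ...) {
  cat("<taxonomy_map>", x$name, "on channel", x$channel, "\n")
  cat("classes:", paste(x$classes, collapse = ", "), "\n")
  invisible(x)
}

#' Map raw codes to taxonomy classes
#'
#' Applies a taxonomy's total mapping to a vector of raw codes. The sentinel
#' `"unlabeled"` maps to `NA` (uncovered seconds carry no class); any other
#' code outside the taxonomy's vocabulary is an error naming the code.
#'
#' @param labels Character vector of raw codes from the taxonomy's channel.
#' @param tax A [taxonomy_map()].
#' @return Character vector of class names (with `NA` for unlabeled).
#' @export
apply_taxonomy <- function(labels, tax) {
  stopifnot(inherits(tax, "taxonomy_map"))
  out <- unname(tax$rule[labels])
  unknown <- unique(labels[is.na(out) & labels != UNLABELED])
  if (length(unknown) > 0) {
    stop("mapping error: raw code(s) not in taxonomy '", tax$name, "': ",
         paste(unknown, collapse = ", "))
  }
  out
}

#' Attach taxonomy label columns to per-second records
#'
#' Adds one column per taxonomy (`t1`, `t2`, `t3` for the built-ins, or the
#' lower-cased first token of a custom taxonomy name) by reading each
#' taxonomy's channel from the rasterized records.
#'
#' @param seconds Output of [rasterize()] / [rasterize_all()].
#' @param taxonomies List of [taxonomy_map()] objects.
#' @return `seconds` with the label columns appended.
#' @export
label_seconds <- function(seconds,
                          taxonomies = list(taxonomy_map("T1_sedentary"),
                                            taxonomy_map("T2_activity_type"),
                                            taxonomy_map("T3_intensity"))) {
  for (tax in taxonomies) {
    col <- tolower(strsplit(tax$name, "_")[[1]][1])
    seconds[[col]] <- apply_taxonomy(seconds[[tax$channel]], tax)
  }
  seconds
}

#' Read or write a taxonomy map as YAML
#'
#' The YAML layout has fields `name`, `channel`, `classes` and `rule` (a
#' mapping raw code -> class), so site-specific consolidations can be swapped
#' in without code changes.
#'
#' @param path File path.
#' @return For `read_taxonomy`, a `taxonomy_map`.
#' @export
read_taxonomy <- function(path) {
  y <- yaml::read_yaml(path)
  new_taxonomy_map(y$name, y$channel, unlist(y$classes),
                   unlist(y$rule))
}

#' @rdname read_taxonomy
#' @param tax A `taxonomy_map` to serialize.
#' @export
write_taxonomy <- function(tax, path) {
  yaml::write_yaml(list(name = tax$name, channel = tax$channel,
                        classes = as.list(tax$classes),
                        rule = as.list(tax$rule)), path)
  invisible(path)
}
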