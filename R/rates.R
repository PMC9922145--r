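#' The built-in registry of umami-substitutable food categories
#'
#' Eleven food categories for which the published reformulation literature
#' reports how much sodium can be removed, without loss of palatability, when
#' umami substances (monosodium glutamate, calcium diglutamate, inosinate,
#' guanylate) are added. Each category carries a lower and an upper
#' sodium-reduction rate, interpreted as the fraction of that category's sodium
#' that is removed (rate 1.0 means all sodium in the category is eliminated),
#' and a food-code match specification against the UK Nutrient Databank coding
#' scheme: either a set of main-group codes or a set of digit prefixes matched
#' against the digit part of the subgroup food code.
#'
#' Six categories (chicken broth, salted fish, miso, soy sauce, vegetable soup,
#' salted vegetable) have no concrete code assignment in the source literature,
#' which identifies them only as "codes whose first one or two digits
#' correspond". The built-in registry deliberately ships these with *empty*
#' match specifications — inventing codes would silently change results — so
#' they never match until the user supplies survey-version-specific codes, e.g.
#' via [synthetic_prefix_overlay()] for simulation work.
#'
#' @return A tibble with one row per category: `category_id`, `name`,
#'   `main_groups` (list of integer main-group codes), `prefixes` (list of
#'   digit-string prefixes), `lower_rate`, `upper_rate` (fractions in
#'   \[0, 1\]), and `substances` (free-text metadata).
#' @seealso [load_registry()], [match_category()], [synthetic_prefix_overlay()]
#' @examples
#' default_registry()
#' @export
default_registry <- function() {
  reg <- tibble::tibble(
    category_id = 1:11,
    name = c(
      "Cheese", "Sausage", "Chicken broth", "Salted fish", "Miso",
      "Soy sauce", "Snack", "Vegetable soup", "Potato chips",
      "Salted vegetable", "Butter"
    ),
    main_groups = list(
      14L, c(22L, 30L), integer(), integer(), integer(),
      integer(), 42L, integer(), 38L, integer(), 17L
    ),
    prefixes = list(
      character(), character(), character(), character(), character(),
      character(), character(), character(), character(), character(),
      character()
    ),
    lower_rate = c(0.54, 0.17, 0.11, 0.30, 0.15, 0.40, 0.51, 0.17, 0.30, 0.55, 1.00),
    upper_rate = c(1.00, 0.75, 0.38, 0.40, 0.35, 0.61, 0.51, 0.40, 0.30, 0.55, 1.00),
    substances = c(
      "MSG", "MSG, CDG, Inosinate", "MSG, CDG", "MSG, Inosinate",
      "MSG, Inosinate, Guanylate", "MSG, Inosinate, Guanylate",
      "MSG, Inosinate, Guanylate", "Glutamates, CDG", "MSG", "MSG", "MSG"
    )
  )
  attr(reg, "provenance") <-
    "Literature-derived umami sodium-reduction rates by UK Nutrient Databank food category"
  validate_registry(reg)
}

#' Validate a category-rate registry
#'
#' Checks structure and the load-time invariants: unique category ids, rates in
#' \[0, 1\] with `lower_rate <= upper_rate`, and a disjoint match specification
#' — no food code can resolve to two rules. Disjointness is enforced by
#' rejecting (a) a main-group code claimed by two rules, (b) a prefix that
#' equals, extends or is extended by a prefix of another rule, and (c) a prefix
#' equal to the digit string of a main-group code claimed by another rule.
#' Empty match specifications are permitted: such categories simply never match
#' (see [default_registry()]).
#'
#' @param registry A registry tibble as returned by [default_registry()] or
#'   [load_registry()].
#' @return The registry, invisibly unchanged, if valid; otherwise an error
#'   naming the offending rule(s).
#' @export
validate_registry <- function(registry) {
  check_columns(
    registry,
    c("category_id", "name", "main_groups", "prefixes", "lower_rate", "upper_rate"),
    "registry"
  )
  if (anyDuplicated(registry$category_id)) {
    abort_saltscen("duplicate category_id in registry", "saltscen_registry_error")
  }
  bad_rate <- registry$lower_rate < 0 | registry$upper_rate > 1 |
    registry$lower_rate > registry$upper_rate
  if (any(bad_rate)) {
    abort_saltscen(
      sprintf(
        "invalid reduction rates (need 0 <= lower <= upper <= 1) for: %s",
        paste(registry$name[bad_rate], collapse = ", ")
      ),
      "saltscen_registry_error"
    )
  }

  mg <- tidyr::unnest(
    dplyr::select(registry, "name", value = "main_groups"), "value"
  )
  if (anyDuplicated(mg$value)) {
    dup <- mg$value[duplicated(mg$value)][1]
    abort_saltscen(
      sprintf(
        "main group %d is claimed by rules: %s", dup,
        paste(unique(mg$name[mg$value == dup]), collapse = " and ")
      ),
      "saltscen_registry_error"
    )
  }
  px <- tidyr::unnest(
    dplyr::select(registry, "name", value = "prefixes"), "value"
  )
  if (nrow(px) > 1) {
    for (a in seq_len(nrow(px) - 1)) {
      for (b in seq(a + 1, nrow(px))) {
        pa <- px$value[a]
        pb <- px$value[b]
        if (startsWith(pa, pb) || startsWith(pb, pa)) {
          abort_saltscen(
            sprintf(
              "prefixes '%s' (%s) and '%s' (%s) can match the same food code",
              pa, px$name[a], pb, px$name[b]
            ),
            "saltscen_registry_error"
          )
        }
      }
    }
  }
  if (nrow(px) > 0 && nrow(mg) > 0) {
    clash <- merge(
      transform(px, key = value),
      transform(mg, key = as.character(value)),
      by = "key", suffixes = c(".px", ".mg")
    )
    clash <- clash[clash$name.px != clash$name.mg, , drop = FALSE]
    if (nrow(clash) > 0) {
      abort_saltscen(
        sprintf(
          "prefix '%s' (%s) collides with main group %s (%s)",
          clash$key[1], clash$name.px[1], clash$key[1], clash$name.mg[1]
        ),
        "saltscen_registry_error"
      )
    }
  }
  invisible(registry)
}

#' Read a category-rate registry from a YAML config file
#'
#' The file stores rates in percent, as published tables print them; they are
#' converted to fractions on load. With `path = NULL` the built-in
#' [default_registry()] is returned.
#'
#' @param path Path to a YAML registry file, or `NULL` for the built-in
#'   defaults.
#' @return A validated registry tibble (see [default_registry()]).
#' @section File format:
#' ```yaml
#' provenance: free text
#' categories:
#'   - id: 1
#'     name: Cheese
#'     main_groups: [14]
#'     prefixes: []
#'     lower_pct: 54
#'     upper_pct: 100
#'     substances: MSG
#' ```
#' @export
load_registry <- function(path = NULL) {
  if (is.null(path)) {
    return(default_registry())
  }
  if (!file.exists(path)) {
    abort_saltscen(sprintf("registry file not found: %s", path), "saltscen_io_error")
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw$categories)) {
    abort_saltscen("registry file has no 'categories' entry", "saltscen_registry_error")
  }
  rows <- purrr::map(raw$categories, function(cat) {
    for (fld in c("id", "name", "lower_pct", "upper_pct")) {
      if (is.null(cat[[fld]])) {
        abort_saltscen(
          sprintf("registry category missing field '%s'", fld),
          "saltscen_registry_error"
        )
      }
    }
    if (cat$lower_pct < 0 || cat$upper_pct > 100 || cat$lower_pct > cat$upper_pct) {
      abort_saltscen(
        sprintf(
          "category '%s': rates must satisfy 0 <= lower <= upper <= 100 (percent)",
          cat$name
        ),
        "saltscen_registry_error"
      )
    }
    tibble::tibble(
      category_id = as.integer(cat$id),
      name = as.character(cat$name),
      main_groups = list(as.integer(unlist(cat$main_groups))),
      prefixes = list(as.character(unlist(cat$prefixes))),
      lower_rate = cat$lower_pct / 100,
      upper_rate = cat$upper_pct / 100,
      substances = as.character(cat$substances %||% NA_character_)
    )
  })
  reg <- dplyr::bind_rows(rows)
  attr(reg, "provenance") <- raw$provenance %||% NA_character_
  validate_registry(reg)
}

#' Write a registry to a YAML config file
#'
#' Inverse of [load_registry()]: rates are written back in percent. A
#' `load_registry(write_registry(reg, f))` round trip is the identity.
#'
#' @param registry A validated registry tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  validate_registry(registry)
  cats <- purrr::pmap(registry, function(category_id, name, main_groups,
                                         prefixes, lower_rate, upper_rate,
                                         substances = NA_character_, ...) {
    list(
      id = as.integer(category_id),
      name = name,
      main_groups = as.list(as.integer(main_groups)),
      prefixes = as.list(as.character(prefixes)),
      lower_pct = lower_rate * 100,
      upper_pct = upper_rate * 100,
      substances = substances
    )
  })
  out <- list(
    provenance = attr(registry, "provenance") %||% NA_character_,
    categories = cats
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Resolve food codes to umami-substitutable categories
#'
#' A record matches a rule by its main-group code first; if no rule claims the
#' main group, the digit part of the subgroup food code (letter suffix
#' stripped) is compared against the registry prefixes. Registry validation
#' guarantees at most one rule can match, so the result is deterministic.
#'
#' @param food_code Character vector of subgroup food codes: digits with an
#'   optional trailing letter suffix (e.g. `"14R"`).
#' @param main_group_code Integer vector of main food-group codes, recycled
#'   against `food_code`.
#' @param registry A validated registry tibble.
#' @return Integer vector of `category_id`s, `NA` where the food is not
#'   umami-substitutable.
#' @examples
#' match_category(c("14R", "30B", "99A"), c(14L, 30L, 99L), default_registry())
#' @export
match_category <- function(food_code, main_group_code, registry) {
  validate_registry(registry)
  n <- max(length(food_code), length(main_group_code))
  food_code <- rep_len(as.character(food_code), n)
  main_group_code <- rep_len(as.integer(main_group_code), n)

  mg_tbl <- tidyr::unnest(
    dplyr::select(registry, "category_id", value = "main_groups"), "value"
  )
  mg_map <- stats::setNames(mg_tbl$category_id, mg_tbl$value)
  out <- unname(mg_map[as.character(main_group_code)])

  px_tbl <- tidyr::unnest(
    dplyr::select(registry, "category_id", value = "prefixes"), "value"
  )
  if (nrow(px_tbl) > 0 && anyNA(out)) {
    digits <- stringr::str_extract(food_code, "^[0-9]+")
    digits[is.na(digits)] <- ""
    for (i in seq_len(nrow(px_tbl))) {
      hit <- is.na(out) & startsWith(digits, px_tbl$value[i])
      out[hit] <- px_tbl$category_id[i]
    }
  }
  as.integer(out)
}

#' Synthetic prefix overlay for the unmapped categories
#'
#' Six built-in categories ship without food-code assignments because the rate
#' literature does not pin them to concrete codes (see [default_registry()]).
#' For simulation and testing, this overlay assigns *synthetic placeholder*
#' prefixes (50–55, outside the code ranges the mapped rules claim) so that
#' every category is matchable. The placeholders are not real survey codes and
#' must not be used against real diary extracts; supply your own
#' survey-version-specific registry file instead.
#'
#' @param registry Registry to overlay; defaults to [default_registry()].
#' @return The registry with empty match specifications replaced by synthetic
#'   prefixes, revalidated.
#' @export
synthetic_prefix_overlay <- function(registry = default_registry()) {
  placeholders <- c(
    "Chicken broth" = "50", "Salted fish" = "51", "Miso" = "52",
    "Soy sauce" = "53", "Vegetable soup" = "54", "Salted vegetable" = "55"
  )
  empty <- lengths(registry$main_groups) == 0 & lengths(registry$prefixes) == 0
  for (i in which(empty)) {
    ph <- placeholders[[registry$name[i]]]
    if (is.null(ph)) {
      # unmapped category outside the built-in six: derive an unused prefix
      ph <- as.character(55 + i)
    }
    registry$prefixes[[i]] <- ph
  }
  validate_registry(registry)
  registry
}

`%||%` <- function(x, y) if (is.null(x)) y else x
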