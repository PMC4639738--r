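#' @importFrom rlang .data
NULL

#' Closed category sets used throughout the package
#'
#' Deprivation classes follow the standard coding for captive chimpanzee
#' deprivation histories: ND (zoo-born, mother-reared, non-deprived), EMD
#' (wild-caught, early maternally deprived, peer-reared), ELD / LLD
#' (ex-laboratory, early / late onset of long-term solitary housing), LMD
#' (late maternally deprived) and a catch-all "other".
#'
#' @name categories
#' @keywords internal
deprivation_classes <- function() c("ND", "EMD", "ELD", "LLD", "LMD", "other")

#' @rdname categories
#' @keywords internal
sex_levels <- function() c("female", "male")

#' @rdname categories
#' @keywords internal
age_class_levels <- function() c("mature", "old")

roster_columns <- function() {
  c("id", "group_id", "sex", "age_class", "deprivation_class")
}

#' Build a validated roster of study subjects
#'
#' A roster is a tibble with one row per individual and columns `id`,
#' `group_id`, `sex` (`female`/`male`), `age_class` (`mature`/`old`) and
#' `deprivation_class` (see [deprivation_classes()]). It is the reference
#' against which scan records, networks and measure tables are checked.
#'
#' @param individuals data frame with at least the five roster columns.
#' @return A tibble of class `roster`.
#' @export
#' @examples
#' roster(data.frame(
#'   id = c("A", "B"), group_id = "G1", sex = c("female", "male"),
#'   age_class = "mature", deprivation_class = c("ND", "EMD")
#' ))
roster <- function(individuals) {
  individuals <- tibble::as_tibble(individuals)
  missing <- setdiff(roster_columns(), names(individuals))
  if (length(missing) > 0) {
    stop("roster format error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  individuals <- dplyr::mutate(
    individuals,
    dplyr::across(dplyr::all_of(roster_columns()), as.character)
  )
  validate_roster(individuals)
  class(individuals) <- c("roster", class(individuals))
  individuals
}

validate_roster <- function(individuals) {
  if (nrow(individuals) == 0) {
    stop("roster validation error: roster is empty", call. = FALSE)
  }
  dup <- unique(individuals$id[duplicated(individuals$id)])
  if (length(dup) > 0) {
    stop("roster validation error: duplicate id(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  check_levels <- function(values, allowed, field) {
    bad <- setdiff(unique(values), allowed)
    if (length(bad) > 0) {
      stop("roster validation error: unknown ", field, " label(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  check_levels(individuals$sex, sex_levels(), "sex")
  check_levels(individuals$age_class, age_class_levels(), "age_class")
  check_levels(individuals$deprivation_class, deprivation_classes(),
               "deprivation_class")
  sizes <- table(individuals$group_id)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    stop("roster validation error: group(s) with fewer than 2 individuals: ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  invisible(individuals)
}

#' Group identifiers present in a roster
#' @param x a [roster()].
#' @return Character vector of group ids, in order of first appearance.
#' @export
group_ids <- function(x) {
  stopifnot(inherits(x, "roster"))
  unique(x$group_id)
}

#' Read / write a roster CSV
#'
#' The file is a UTF-8 CSV with a header row naming the five roster columns
#' (`id,group_id,sex,age_class,deprivation_class`; extra columns such as
#' `birth_year` are carried through untouched).
#'
#' @param path file path.
#' @return `read_roster()` returns a validated [roster()];
#'   `write_roster()` returns `path` invisibly.
#' @export
read_roster <- function(path) {
  if (!file.exists(path)) {
    stop("roster file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  roster(df)
}

#' @rdname read_roster
#' @param x a [roster()].
#' @export
write_roster <- function(x, path) {
  stopifnot(inherits(x, "roster"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Age class from sex and age in years
#'
#' Adults are `mature` (females 13--33 y, males 16--33 y) or `old` (> 33 y);
#' younger animals are not part of the adult-only sampling scheme and raise
#' an error.
#'
#' @param sex `"female"` or `"male"` (recycled against `age_years`).
#' @param age_years numeric age in years.
#' @return Character vector of `"mature"` / `"old"`.
#' @export
#' @examples
#' age_class_from_age("female", c(14, 40))
age_class_from_age <- function(sex, age_years) {
  n <- max(length(sex), length(age_years))
  sex <- rep_len(as.character(sex), n)
  age_years <- rep_len(age_years, n)
  if (!all(sex %in% sex_levels())) {
    stop("unknown sex label", call. = FALSE)
  }
  lower <- ifelse(sex == "female", 13, 16)
  out <- rep(NA_character_, n)
  out[age_years > 33] <- "old"
  out[age_years >= lower & age_years <= 33] <- "mature"
  if (anyNA(out)) {
    stop("age below the adult threshold for this sex: individuals younger ",
         "than 13 y (females) / 16 y (males) are not sampled", call. = FALSE)
  }
  out
}
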