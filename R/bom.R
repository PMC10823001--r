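#' Read a bill-of-materials CSV
#'
#' The packaged fixture transcribes the materials list for a 50-wheel,
#' 3-logger build of the open-source 3D-printed running wheel; users can
#' cost their own builds by supplying a CSV with the same columns
#' (`name`, `category`, `unit_cost`, `quantity`, `line_total`; categories
#' `MAJOR_EQUIPMENT` or `CONSUMABLE`).
#'
#' @param path CSV path; defaults to the packaged materials list.
#' @return `data.frame` of BOM items.
#' @export
read_bom <- function(path = system.file("extdata", "bom_materials.csv",
                                        package = "wheelrun")) {
  items <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "category", "unit_cost", "quantity", "line_total")
  if (!all(need %in% names(items)))
    stop_validation(paste("BOM file needs columns:",
                          paste(need, collapse = ", ")))
  if (!all(items$category %in% c("MAJOR_EQUIPMENT", "CONSUMABLE")))
    stop_validation("BOM categories must be MAJOR_EQUIPMENT or CONSUMABLE")
  items
}

cents <- function(x) as.integer(round(x * 100))

#' Validate a bill of materials and total it
#'
#' Checks every line total against unit cost times quantity (to the cent)
#' and sums by category. All currency arithmetic is in integer cents, so
#' totals are exact.
#'
#' @param items BOM `data.frame` (see [read_bom()]).
#' @return list with `by_category` (`data.frame`: `category`,
#'   `total_usd`) and `grand_total_usd`.
#' @export
bom_totals <- function(items = read_bom()) {
  if (nrow(items) == 0L)
    return(list(by_category = data.frame(category = character(),
                                         total_usd = numeric()),
                grand_total_usd = 0))
  lt <- cents(items$line_total)
  expect <- cents(items$unit_cost) * as.integer(items$quantity)
  bad <- which(abs(lt - expect) > 1L) # Table-style rounding: 1 cent slack
  if (length(bad) > 0L)
    stop_validation(sprintf(
      "BOM line total inconsistent with unit cost x quantity for: %s",
      paste(items$name[bad], collapse = ", ")))
  by_cat <- stats::aggregate(lt, by = list(category = items$category),
                             FUN = sum)
  names(by_cat)[2] <- "total_cents"
  list(by_category = data.frame(category = by_cat$category,
                                total_usd = by_cat$total_cents / 100),
       grand_total_usd = sum(lt) / 100)
}

#' The reference 3D-print plan for one wheel
#'
#' Filament mass and print time per part: the wheel itself, the base, a
#' set of four locking nuts, and the axle. One complete wheel needs
#' 144 g of PETG and 477 min (7 h 57 min) of print time.
#'
#' @return `data.frame`: `part`, `mass_g`, `time_min`.
#' @export
print_plan <- function() {
  data.frame(part = c("WHEEL", "BASE", "NUT_SET_OF_4", "AXLE"),
             mass_g = c(96, 38, 4, 6),
             time_min = c(4L * 60L + 20L, 60L + 45L, 28L, 60L + 24L),
             stringsAsFactors = FALSE)
}

#' Print-plan totals for a build
#'
#' Per-wheel filament mass and print time are exact sums over the four
#' parts; each wheel is locked by a set of four printed nuts, so a build
#' of `n_wheels` wheels needs `4 * n_wheels` nuts. Time arithmetic is in
#' integer minutes.
#'
#' @param parts print-plan `data.frame` (see [print_plan()]); must contain
#'   exactly one entry per part.
#' @param n_wheels number of wheels in the build.
#' @return list: `per_wheel_mass_g`, `per_wheel_time_min`, `build_mass_g`,
#'   `build_time_min`, `nut_count`.
#' @export
print_plan_totals <- function(parts = print_plan(), n_wheels = 1L) {
  need <- c("WHEEL", "BASE", "NUT_SET_OF_4", "AXLE")
  if (!setequal(parts$part, need) || nrow(parts) != 4L)
    stop_validation(paste("print plan must contain exactly one entry per",
                          "part:", paste(need, collapse = ", ")))
  if (any(parts$mass_g < 0) || any(parts$time_min < 0))
    stop_validation("masses and times must be >= 0")
  if (n_wheels < 0) stop_validation("`n_wheels` must be >= 0")
  mass <- sum(parts$mass_g)
  tmin <- sum(as.integer(parts$time_min))
  list(per_wheel_mass_g = mass, per_wheel_time_min = tmin,
       build_mass_g = mass * n_wheels, build_time_min = tmin * n_wheels,
       nut_count = 4L * as.integer(n_wheels))
}
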