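#' Formulate a mixture recipe from selected chemicals
#'
#' Turns a prioritized chemical set into a synthesis recipe: each
#' component's proportion is scaled relative to the most abundant selected
#' chemical (the reference component gets 1), preserving the environmental
#' concentration ratios. `percent_of_source` reports each component's share
#' of the full source mixture's total detected concentration, so
#' [coverage_percent()] states how much of the source the recipe covers.
#'
#' Chemicals that cannot be synthesized (e.g. no analytical standard is
#' available) are dropped via `exclude`; proportions are then re-scaled to
#' the remaining maximum and a message records the exclusion.
#'
#' @param selected character vector of CAS numbers to include.
#' @param chemicals the source [chemical_table()].
#' @param name mixture display name.
#' @param exclude CAS numbers to drop from `selected`, with a message.
#' @return A list of class `mixture_recipe`: `mixture_name`, `components`
#'   (data.frame `cas`, `name`, `concentration`, `relative_proportion`,
#'   `percent_of_source`, ordered by decreasing proportion),
#'   `reference_cas`.
#' @export
#' @examples
#' ct <- chemical_table(c("a", "b", "c"), c("1-1", "2-2", "3-3"),
#'                      c(100, 50, 25))
#' formulate(c("1-1", "2-2", "3-3"), ct, "demo")
formulate <- function(selected, chemicals, name = "mixture",
                      exclude = character()) {
  stopifnot(inherits(chemicals, "chemical_table"))
  selected <- as.character(selected)
  if (!length(selected)) stop("no chemicals selected", call. = FALSE)
  drop <- intersect(selected, exclude)
  if (length(drop)) {
    message("excluding from ", name, ": ", paste(drop, collapse = ", "),
            " (proportions re-scaled to remaining maximum)")
    selected <- setdiff(selected, drop)
    if (!length(selected)) stop("all selected chemicals excluded",
                                call. = FALSE)
  }
  idx <- match(selected, chemicals$cas)
  if (anyNA(idx)) {
    stop("selected CAS absent from chemical table: ",
         paste(selected[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  conc <- chemicals$concentration[idx]
  if (any(conc <= 0)) {
    stop("selected chemical with zero concentration: ",
         paste(selected[conc <= 0], collapse = ", "), call. = FALSE)
  }
  total <- total_concentration(chemicals)
  comp <- data.frame(cas = selected,
                     name = chemicals$name[idx],
                     concentration = conc,
                     relative_proportion = conc / max(conc),
                     percent_of_source = 100 * conc / total,
                     stringsAsFactors = FALSE)
  comp <- comp[order(-comp$relative_proportion, comp$cas), , drop = FALSE]
  rownames(comp) <- NULL
  structure(list(mixture_name = name, components = comp,
                 reference_cas = comp$cas[1]),
            class = "mixture_recipe")
}

#' Percent of the source mixture covered by a recipe
#'
#' @param recipe a [formulate()] result.
#' @return Scalar percent: sum of the components' shares of the source
#'   mixture's total concentration.
#' @export
coverage_percent <- function(recipe) {
  stopifnot(inherits(recipe, "mixture_recipe"))
  sum(recipe$components$percent_of_source)
}

#' @export
print.mixture_recipe <- function(x, ...) {
  cat("mixture recipe '", x$mixture_name, "' (",
      nrow(x$components), " components, covers ",
      sprintf("%.1f", coverage_percent(x)), "% of source)\n", sep = "")
  print(x$components[c("cas", "name", "relative_proportion",
                       "percent_of_source")], digits = 4)
  invisible(x)
}
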