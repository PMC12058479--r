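#' Normalize reported drug names to active ingredients
#'
#' Fills the `ingredient` column of the drug table: the raw name is
#' upper-cased, trimmed, squeezed of internal whitespace and stripped of a
#' trailing salt/ester suffix (see [default_salt_suffixes()]); the cleaned
#' name is then looked up in the brand-to-ingredient map. Names absent from
#' the map keep their cleaned form, so an empty map is legal and the
#' operation is idempotent.
#'
#' @param rs A [report_set].
#' @param name_map Optional tibble/data frame with columns `brand` and
#'   `ingredient` (case-insensitive match on the cleaned brand name), or
#'   `NULL` for no mapping.
#' @param salt_suffixes Character vector of suffix words stripped from the
#'   end of a cleaned name. The default list is editable because brand
#'   consolidation is site-specific.
#' @return The report set with `ingredient` filled.
#' @export
normalize_drug_names <- function(rs, name_map = NULL,
                                 salt_suffixes = default_salt_suffixes()) {
  stopifnot(is_report_set(rs))
  cleaned <- clean_drug_name(rs$drugs$name_raw, salt_suffixes)
  if (!is.null(name_map) && nrow(name_map) > 0) {
    if (!all(c("brand", "ingredient") %in% names(name_map))) {
      abort("name_map needs columns `brand` and `ingredient`")
    }
    map <- setNames(
      clean_drug_name(name_map$ingredient, salt_suffixes),
      clean_drug_name(name_map$brand, salt_suffixes)
    )
    hit <- cleaned %in% names(map)
    cleaned[hit] <- unname(map[cleaned[hit]])
  }
  rs$drugs$ingredient <- cleaned
  add_provenance(rs, "normalize_drug_names",
                 paste0(dplyr::n_distinct(cleaned), " distinct ingredients"))
}

#' @rdname normalize_drug_names
#' @param x Character vector of raw drug names.
#' @export
clean_drug_name <- function(x, salt_suffixes = default_salt_suffixes()) {
  out <- stringr::str_to_upper(stringr::str_trim(x))
  out <- stringr::str_replace_all(out, "\\s+", " ")
  if (length(salt_suffixes) > 0) {
    pat <- paste0("( (", paste(salt_suffixes, collapse = "|"), "))+$")
    out <- stringr::str_remove(out, pat)
  }
  out
}

#' @rdname normalize_drug_names
#' @export
default_salt_suffixes <- function() {
  c("CALCIUM", "SODIUM", "POTASSIUM", "MAGNESIUM", "HCL", "HYDROCHLORIDE",
    "MESYLATE", "MESILATE", "MALEATE", "TARTRATE", "BITARTRATE", "SUCCINATE",
    "FUMARATE", "CITRATE", "SULFATE", "SULPHATE", "PHOSPHATE", "ACETATE",
    "BESYLATE", "BROMIDE", "DIHYDRATE", "MONOHYDRATE", "TRIHYDRATE")
}
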