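#' Trait specification
#'
#' Declares how a trait was scored, which determines the analysis path:
#' `replicated_quantitative` traits (up to 3 plants per accession x
#' environment) go through the random-effects MET model, WAASB stability and
#' GWEIS; `accession_mean_quantitative` traits (one value per accession x
#' environment) through fixed two-way ANOVA and the GGE/AEC stability index;
#' `qualitative` traits are categorical with declared levels.
#'
#' @param name trait name
#' @param kind one of "replicated_quantitative", "accession_mean_quantitative",
#'   "qualitative"
#' @param categories character vector of levels (qualitative only)
#' @return a `trait_spec` object
#' @export
trait_spec <- function(name,
                       kind = c("replicated_quantitative",
                                "accession_mean_quantitative", "qualitative"),
                       categories = NULL) {
  kind <- match.arg(kind)
  if (kind == "qualitative") {
    if (is.null(categories) || length(categories) < 2L)
      stop("qualitative trait '", name, "' needs >= 2 declared categories")
  } else if (!is.null(categories)) {
    stop("categories only apply to qualitative traits")
  }
  structure(list(name = name, kind = kind, categories = categories),
            class = "trait_spec")
}

#' Long-format multi-environment-trial phenotype table
#'
#' @param records data.frame with columns accession, environment, replicate,
#'   trait, value
#' @param trait_specs named list of [trait_spec()] objects covering every
#'   trait present
#' @return a `met_table`: validated data.frame with attribute `trait_specs`
#' @export
met_table <- function(records, trait_specs) {
  req <- c("accession", "environment", "replicate", "trait", "value")
  if (!all(req %in% names(records)))
    stop("phenotype table needs columns: ", paste(req, collapse = ", "))
  records <- as.data.frame(records)[, req]
  records$accession <- as.character(records$accession)
  records$environment <- as.character(records$environment)
  records$replicate <- as.integer(records$replicate)
  records$trait <- as.character(records$trait)
  if (is.list(trait_specs) && !inherits(trait_specs, "trait_spec")) {
    nm <- vapply(trait_specs, function(s) s$name, character(1))
    names(trait_specs) <- nm
  }
  unknown <- setdiff(unique(records$trait), names(trait_specs))
  if (length(unknown)) stop("unknown trait(s): ", paste(unknown, collapse = ", "))
  for (tr in unique(records$trait)) {
    sp <- trait_specs[[tr]]
    v <- records$value[records$trait == tr]
    if (sp$kind == "qualitative") {
      bad <- setdiff(unique(as.character(v[!is.na(v)])), sp$categories)
      if (length(bad))
        stop("trait '", tr, "': category outside declared levels: ",
             paste(bad, collapse = ", "))
    } else {
      vn <- suppressWarnings(as.numeric(v))
      if (any(is.na(vn) & !is.na(v)))
        stop("trait '", tr, "': non-numeric value for quantitative trait")
      if (sp$kind == "accession_mean_quantitative") {
        sub <- records[records$trait == tr, ]
        n <- table(paste(sub$accession, sub$environment, sep = "\r"))
        if (any(n > 1L))
          stop("trait '", tr, "': accession-mean trait has multiple values ",
               "per accession x environment")
      }
    }
  }
  structure(records, trait_specs = trait_specs, class = c("met_table", "data.frame"))
}

#' Read a long-format phenotype CSV
#'
#' Expects columns accession, environment, replicate, trait, value; values are
#' validated against the supplied trait specifications.
#'
#' @param path CSV path
#' @param trait_specs named list of [trait_spec()]
#' @return a [met_table()]
#' @export
read_phenotypes <- function(path, trait_specs) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, na.strings = c("NA", ".", "-9"))
  met_table(as.data.frame(dt), trait_specs)
}

#' Write a phenotype table to CSV (round-trips with [read_phenotypes()])
#' @param met a [met_table()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_phenotypes <- function(met, path) {
  data.table::fwrite(as.data.frame(met), path, na = "NA", quote = FALSE)
  invisible(path)
}

#' Accession x environment mean table for one trait
#' @param met a [met_table()]
#' @param trait trait name
#' @return numeric matrix accessions x environments of cell means (NA where
#'   unobserved)
#' @export
trait_cell_means <- function(met, trait) {
  sub <- met[met$trait == trait & !is.na(met$value), ]
  if (!nrow(sub)) stop("no observations for trait ", trait)
  v <- as.numeric(sub$value)
  acc <- sort(unique(sub$accession)); env <- sort(unique(sub$environment))
  m <- matrix(NA_real_, length(acc), length(env), dimnames = list(acc, env))
  agg <- tapply(v, list(sub$accession, sub$environment), mean)
  m[rownames(agg), colnames(agg)] <- agg
  m
}
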