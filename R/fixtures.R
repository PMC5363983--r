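## Packaged transcriptions of the experimental summary tables: measured
## temperatures, development/brood summaries, contingency counts and the
## reproduction-test comparison.

.fixCache <- new.env(parent = emptyenv())

#' Load the packaged experiment fixtures
#'
#' Transcribed summaries of the temperature and food life-cycle
#' experiments: measured mean temperatures per regime, development-time
#' and brood-size summaries (mean, SD, n), alive/dead and female/male
#' counts per treatment with the p-values reported alongside them, and the
#' simulated-vs-theoretical reproduction comparison. Loading validates
#' completeness and internal consistency of the count tables.
#'
#' @param path Optional path to an alternative fixture YAML.
#' @return Nested named list, see the YAML file in `inst/extdata`.
#' @export
#' @examples
#' experimentFixtures()$measured_temperatures$`20C`$mean
experimentFixtures <- function(path = NULL) {
  default <- is.null(path)
  if (default && !is.null(.fixCache$fix)) return(.fixCache$fix)
  if (default)
    path <- system.file("extdata", "experiment_fixtures.yaml",
                        package = "NitocraSim", mustWork = TRUE)
  fix <- yaml::yaml.load_file(path)
  need <- c("measured_temperatures", "development_summaries", "contingency",
            "reproduction_comparison")
  miss <- setdiff(need, names(fix))
  if (length(miss))
    stop("fixture file incomplete, missing: ", paste(miss, collapse = ", "))
  for (nm in names(fix$contingency)) {
    ct <- fix$contingency[[nm]]
    counts <- do.call(rbind, ct$counts)
    if (ncol(counts) != 2 || nrow(counts) != length(ct$rows))
      stop("malformed contingency fixture '", nm, "'")
    if (any(counts < 0)) stop("negative count in fixture '", nm, "'")
  }
  if (default) .fixCache$fix <- fix
  fix
}

#' Fetch a contingency-count fixture as a matrix
#'
#' @param name Fixture name, e.g. `"temperature-sexratio"`,
#'   `"food-naupliar-mortality"`; see `names(experimentFixtures()$contingency)`.
#' @return Integer matrix with row/column labels; the reported p-value is
#'   attached as attribute `reported_p`.
#' @export
#' @examples
#' fixtureTable("temperature-sexratio")
fixtureTable <- function(name) {
  fix <- experimentFixtures()
  if (!name %in% names(fix$contingency))
    stop("unknown fixture '", name, "'; available: ",
         paste(names(fix$contingency), collapse = ", "))
  ct <- fix$contingency[[name]]
  m <- do.call(rbind, ct$counts)
  storage.mode(m) <- "integer"
  dimnames(m) <- list(unlist(ct$rows), unlist(ct$columns))
  attr(m, "reported_p") <- ct$reported_p
  m
}
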