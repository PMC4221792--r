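#' Load a run configuration from YAML or JSON
#'
#' A configuration supplies either an explicit community (`profile:` with
#' `p` and `g_bp` or `g_mbp`) or a generator spec (`generator:` with `s`,
#' `n`, `skew`, optional `size_range_bp`), never both; optional `params:`
#' overriding the ensemble-analysis defaults (`M_u = 5`, `M_l = 0.3`,
#' `tau = 0.2`, `safety_factor = 2`); and an optional `seed`.  Unknown keys
#' are rejected.
#'
#' @param path File path; format inferred from the extension (`.yaml`,
#'   `.yml` or `.json`).
#' @return A list of class `"distill_config"` with elements `profile`
#'   (a [community_profile()]), `params` (a [distill_params()]), `seed`,
#'   and `raw` (the parsed file, echoed into outputs).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("profile", "generator", "params", "seed")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  has_profile <- !is.null(raw$profile)
  has_gen <- !is.null(raw$generator)
  if (has_profile == has_gen)
    stop("exactly one of 'profile' or 'generator' must be given",
         call. = FALSE)
  seed <- if (is.null(raw$seed)) 1L else as.integer(raw$seed)

  if (has_profile) {
    pf <- raw$profile
    pextra <- setdiff(names(pf), c("p", "g_bp", "g_mbp"))
    if (length(pextra))
      stop("unknown profile key(s): ", paste(pextra, collapse = ", "),
           call. = FALSE)
    if (!is.null(pf$g_bp) && !is.null(pf$g_mbp))
      stop("give genome sizes as 'g_bp' or 'g_mbp', not both", call. = FALSE)
    g <- if (!is.null(pf$g_bp)) as.numeric(pf$g_bp)
         else as.numeric(pf$g_mbp) * 1e6
    profile <- community_profile(pf$p, g)
  } else {
    gn <- raw$generator
    # YAML 1.1 parses a bare key `n` as the boolean FALSE; undo that
    names(gn)[names(gn) %in% c("FALSE", "F")] <- "n"
    gextra <- setdiff(names(gn), c("s", "n", "skew", "size_range_bp"))
    if (length(gextra))
      stop("unknown generator key(s): ", paste(gextra, collapse = ", "),
           call. = FALSE)
    profile <- make_profile(
      s = gn$s, n = gn$n,
      size_range = if (is.null(gn$size_range_bp)) c(1e6, 12e6)
                   else as.numeric(gn$size_range_bp),
      skew = if (is.null(gn$skew)) "uniform" else gn$skew,
      seed = seed
    )
  }

  pdef <- raw$params
  if (!is.null(pdef)) {
    kextra <- setdiff(names(pdef),
                      c("M_u", "M_l", "tau", "safety_factor",
                        "root_assembly", "root_sensed", "coverage_summary"))
    if (length(kextra))
      stop("unknown params key(s): ", paste(kextra, collapse = ", "),
           call. = FALSE)
  }
  getd <- function(nm, default) if (is.null(pdef[[nm]])) default else pdef[[nm]]
  params <- distill_params(
    M_u = getd("M_u", 5), M_l = getd("M_l", 0.3), tau = getd("tau", 0.2),
    safety_factor = getd("safety_factor", 2),
    root_assembly = getd("root_assembly", "max"),
    root_sensed = isTRUE(getd("root_sensed", FALSE)),
    coverage_summary = getd("coverage_summary", "min")
  )
  structure(list(profile = profile, params = params, seed = seed, raw = raw),
            class = "distill_config")
}

#' Write an analysis result to disk
#'
#' Serialises an ensemble, Monte-Carlo or search result as JSON (with the
#' configuration echo, package version and seed) and, for results carrying
#' a capture distribution, a companion TSV flattening it (columns
#' `bitstring`, `index`, `probability`).
#'
#' @param result A `"distill_ensemble"`, `"distill_mc"` or
#'   `"distill_search"` object.
#' @param path Output JSON path; the TSV (if any) takes the same path with
#'   extension `.tsv`.
#' @param config Optional `"distill_config"` echoed into the output.
#' @param seed Optional seed echoed into the output.
#' @return Invisibly, the path written.
#' @export
write_result <- function(result, path, config = NULL, seed = NULL) {
  out <- list(package = "distilseq",
              version = as.character(utils::packageVersion("distilseq")))
  if (!is.null(config)) out$config <- config$raw
  if (!is.null(seed)) out$seed <- seed

  if (inherits(result, "distill_ensemble")) {
    if (!length(result$capture))
      stop("empty capture distribution", call. = FALSE)
    out$kind <- "ensemble"
    out$expected_total_bp <- result$expected_total
    out$expected_total_Gbp <- result$expected_total / 1e9
    out$capture <- as.list(result$capture)
    names(out$capture) <- paste0("q", names(result$capture))
    out$per_genome_capture <- result$per_genome_capture
    out$node_evaluations <- result$node_evaluations
  } else if (inherits(result, "distill_mc")) {
    out$kind <- "monte_carlo"
    out$strategy <- result$strategy
    out$reps <- result$reps
    out$mean_total_bp <- result$mean_total
    out$mean_total_Gbp <- result$mean_total / 1e9
    out$se_total_bp <- result$se_total
    out$capture <- as.list(result$capture)
    names(out$capture) <- paste0("q", names(result$capture))
  } else if (inherits(result, "distill_search")) {
    out$kind <- "search"
    out$strategy <- result$strategy
    out$total_sequenced_bp <- result$total_sequenced
    out$total_sequenced_Gbp <- result$total_sequenced / 1e9
    out$rounds <- result$rounds
    out$max_pools_per_round <- result$max_pools_per_round
    out$predicted_distinct_genomes <- length(result$identified)
    out$identified <- result$identified
    out$missed <- result$missed
  } else {
    stop("unsupported result type", call. = FALSE)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  cap <- out$capture
  if (!is.null(cap)) {
    tsv <- sub("\\.[^.]+$", ".tsv", path)
    df <- data.frame(bitstring = sub("^q", "", names(cap)),
                     index = seq_along(cap),
                     probability = unlist(cap))
    utils::write.table(df, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Re-read a result written by [write_result()]
#'
#' @param path JSON path.
#' @return The parsed list.
#' @export
read_result <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
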