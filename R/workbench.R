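## Command-line workbench: a thin argv-driven front end over the exported
## functions, used by the inst/scripts/evireg launcher.  Subcommands:
## sparse, dense, fuse, evaluate, fixtures.

#' Run the command-line interface
#'
#' `evireg <subcommand> [--flag value ...]`.  Subcommands:
#' \describe{
#'   \item{sparse}{`--ref R.png --sen S.png --detector harris --seed 1
#'     --out T.json`}
#'   \item{dense}{`--ref R.png --sen S.png --measure ncc --out T.json`}
#'   \item{fuse}{`--ref R.png --sen S.png --mode dense --rule pcr6
#'     --out result.json --registered Sc.png --dump-bbas bbas.json`}
#'   \item{evaluate}{`--ref R.png --t-true T1.json --t-est T2.json
#'     --out report.json`}
#'   \item{fixtures}{`--suite default --seed 1 --outdir fixtures/`}
#' }
#'
#' @param args character vector of command-line arguments (e.g.
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return exit status, 0 on success (invisibly).
#' @export
runCLI <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) < 1) stop("usage: evireg <sparse|dense|fuse|evaluate|fixtures> ...")
    cmd <- args[1]
    opts <- .parse_flags(args[-1])
    switch(cmd,
      sparse = .cli_sparse(opts),
      dense = .cli_dense(opts),
      fuse = .cli_fuse(opts),
      evaluate = .cli_evaluate(opts),
      fixtures = .cli_fixtures(opts),
      stop("unknown subcommand: ", cmd))
    0L
  }, error = function(e) {
    message("evireg: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

.parse_flags <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[i + 1], "--"))
      stop("missing value for --", key)
    opts[[key]] <- args[i + 1]
    i <- i + 2
  }
  opts
}

.need <- function(opts, key) {
  if (is.null(opts[[key]])) stop("missing required flag --", key)
  opts[[key]]
}

.cli_sparse <- function(opts) {
  R <- readImageGray(.need(opts, "ref"))
  S <- readImageGray(.need(opts, "sen"))
  seed <- as.integer(opts[["seed"]] %||% "1")
  t <- registerSparse(R, S, .need(opts, "detector"), seed = seed,
                      verbose = TRUE)
  transformToJSON(t, .need(opts, "out"))
}

.cli_dense <- function(opts) {
  R <- readImageGray(.need(opts, "ref"))
  S <- readImageGray(.need(opts, "sen"))
  measure <- toupper(opts[["measure"]] %||% "NCC")
  p <- registerDense(R, S, measure)
  transformToJSON(rigidToMatrix(p), .need(opts, "out"))
}

.cli_fuse <- function(opts) {
  R <- readImageGray(.need(opts, "ref"))
  S <- readImageGray(.need(opts, "sen"))
  res <- registerFused(R, S, mode = opts[["mode"]] %||% "dense",
                       rule = opts[["rule"]] %||% "dempster",
                       seed = as.integer(opts[["seed"]] %||% "1"))
  out <- list(
    rule = res@rule,
    labels = res@labels,
    candidates = lapply(res@candidates,
                        function(t) as.vector(t(t@matrix))),
    channelNCC = res@channelNCC,
    bbaG = as.list(massValues(res@bbaG)),
    bbaE = as.list(massValues(res@bbaE)),
    bbaP = as.list(massValues(res@bbaP)),
    bbaC = as.list(massValues(res@bbaC)),
    combined = list(convention = "row-vector",
                    matrix = as.vector(t(res@transform@matrix))),
    package = as.character(utils::packageVersion("evireg")))
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA),
             .need(opts, "out"))
  if (!is.null(opts[["registered"]]))
    writeImageGray(pmin(pmax(res@registered, 0), 1), opts[["registered"]])
  if (!is.null(opts[["dump-bbas"]])) {
    bb <- list(G = as.list(massValues(res@bbaG)),
               E = as.list(massValues(res@bbaE)),
               P = as.list(massValues(res@bbaP)),
               combined = as.list(massValues(res@bbaC)))
    writeLines(jsonlite::toJSON(bb, auto_unbox = TRUE, digits = NA),
               opts[["dump-bbas"]])
  }
}

.cli_evaluate <- function(opts) {
  R <- readImageGray(.need(opts, "ref"))
  tTrue <- transformFromJSON(.need(opts, "t-true"))
  tEst <- transformFromJSON(.need(opts, "t-est"))
  rep <- evaluateRegistration(R, tTrue, tEst,
                              scale8bit = isTRUE(opts[["scale-8bit"]] == "true"))
  out <- list(aaid = rep@aaid, partition = rep@partition)
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA),
             .need(opts, "out"))
  if (!is.null(opts[["heatmap"]])) {
    p <- rep@partition
    pn <- if (max(p) > 0) p / max(p) else p
    big <- pn[rep(seq_len(nrow(pn)), each = 32),
              rep(seq_len(ncol(pn)), each = 32)]
    writeImageGray(big, opts[["heatmap"]])
  }
}

.cli_fixtures <- function(opts) {
  outdir <- .need(opts, "outdir")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(opts[["seed"]] %||% "1")
  suite <- scenarioSuite(seed)
  for (sc in suite) {
    pair <- scenarioPair(sc)
    writeImageGray(pair$R, file.path(outdir, paste0(sc@name, "_ref.png")))
    writeImageGray(pair$S, file.path(outdir, paste0(sc@name, "_sen.png")))
    scenarioToJSON(sc, file.path(outdir, paste0(sc@name, ".json")))
  }
  message("wrote ", length(suite), " scenarios to ", outdir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
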