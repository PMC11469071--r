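# The four-population expansion model family for Primula vulgaris
# (TR-D, CH-D, EN1-D, EN6-M), including the best-fit history with its
# published point estimates, plus simplified alternates, and a structured
# model-file reader.

#' Best-fit four-population demographic model of the P. vulgaris expansion
#'
#' Encodes the selected out-of-Caucasus expansion history for the four
#' populations spanning the range extremes (TR-D Turkey, CH-D Switzerland,
#' EN1-D easternmost England, EN6-M monomorphic England), with a 2-year
#' generation time and mu = 1.23e-8: TR/Europe split 79,000 ybp with
#' ancestral Ne 13,419 and current TR Ne 95,627; CH/EN split 65,500 ybp; CH
#' contraction 64,000 ybp and recovery 62,300 ybp; EN-lineage contraction
#' 48,000 ybp and recovery 31,000 ybp; EN1/EN6 split 24,000 ybp; EN6
#' contraction 100 ybp. Sizes not printed with the selected model (current CH,
#' EN1, EN6 and bottleneck sizes) are calibrated once from the
#' single-population trajectories and per-population diversity (see the
#' package vignette); they are fixed constants of the template.
#'
#' @return a \linkS4class{DemographicModel}
#' @export
vulgarisModel5 <- function() {
  tpl <- vulgarisTemplates()[["model5"]]
  tpl$build(tpl$par)
}

# fixed (nuisance) constants of the model family
.M5 <- list(
  N_CH = 100000, N_EN1 = 20000, N_EN6 = 500,
  N_EN6_PRE = 8000,          # EN6 size before its ~100 ybp contraction
  N_CH_BOT = 2000,           # CH bottleneck size (64,000-62,300 ybp)
  N_CH_PRE = 20000,          # CH size before its contraction
  N_EN_BOT = 3000,           # EN-lineage bottleneck size (48,000-31,000 ybp)
  N_EN_PRE = 20000,          # EN-lineage size before its contraction
  T_EN6_BOT = 50,            # 100 ybp / 2
  T_EN_REC = 15500,          # 31,000 ybp / 2
  T_EN_BOT = 24000,          # 48,000 ybp / 2
  T_CH_REC = 31150,          # 62,300 ybp / 2
  T_CH_BOT = 32000)          # 64,000 ybp / 2

.build_model5 <- function(par) {
  p <- as.list(par)
  tEN6 <- p$T_EN6_split
  tCH <- tEN6 + p$dT_CH_split
  tTR <- tCH + p$dT_TR_split
  ev <- data.frame(
    time_gen = c(.M5$T_EN6_BOT, tEN6, .M5$T_EN_REC, .M5$T_EN_BOT,
                 .M5$T_CH_REC, .M5$T_CH_BOT, tCH, tTR),
    type = c("size", "split", "size", "size", "size", "size", "split",
             "split"),
    pop  = c("EN6", "EN6", "EN1", "EN1", "CH", "CH", "CH", "EN1"),
    dest = c(NA, "EN1", NA, NA, NA, NA, "EN1", "TR"),
    Ne   = c(.M5$N_EN6_PRE, NA, .M5$N_EN_BOT, .M5$N_EN_PRE, .M5$N_CH_BOT,
             .M5$N_CH_PRE, .M5$N_EN_PRE, p$N_ANC),
    stringsAsFactors = FALSE)
  # size changes on a deme are only meaningful while that deme still exists
  # backward in time; clip vacuous ones when the optimizer proposes younger
  # split times than the fixed bottleneck epochs
  merge_time <- c(EN6 = tEN6, CH = tCH, EN1 = tTR, TR = Inf)
  keep <- ev$type == "split" | ev$time_gen < merge_time[ev$pop]
  ev <- ev[keep, , drop = FALSE]
  DemographicModel(c("TR", "CH", "EN1", "EN6"),
                   c(p$N_TR, .M5$N_CH, .M5$N_EN1, .M5$N_EN6),
                   ev, mu = 1.23e-8, generationTime = 2)
}

.report_model5 <- function(par) {
  tEN6 <- par[["T_EN6_split"]]
  tCH <- tEN6 + par[["dT_CH_split"]]
  tTR <- tCH + par[["dT_TR_split"]]
  c(T_TR_split_years = tTR * 2,
    T_CH_split_years = tCH * 2,
    T_EN6_split_years = tEN6 * 2,
    N_TR = par[["N_TR"]],
    N_ANC = par[["N_ANC"]])
}

#' Demographic model templates for the expansion model family
#'
#' Returns \code{\link{modelTemplate}}s over the four-population system:
#' \code{"model5"} is the selected history (free: current TR size, ancestral
#' root size and the three split times, the later two as positive increments
#' so event order is preserved); \code{"nobottleneck"} drops all size-change
#' events; \code{"singlebottleneck"} keeps only the EN-lineage bottleneck.
#' The two alternates are simplified stand-ins forming a testable family with
#' the same parameter grammar.
#'
#' @return named list of \code{\link{modelTemplate}}s
#' @export
vulgarisTemplates <- function() {
  par <- c(N_TR = 95627, N_ANC = 13419, T_EN6_split = 12000,
           dT_CH_split = 20750, dT_TR_split = 6750)
  lower <- c(N_TR = 5000, N_ANC = 500, T_EN6_split = 1000,
             dT_CH_split = 500, dT_TR_split = 250)
  upper <- c(N_TR = 1e6, N_ANC = 2e5, T_EN6_split = 60000,
             dT_CH_split = 80000, dT_TR_split = 80000)
  m5 <- modelTemplate("model5", par, lower, upper, .build_model5,
                      report = .report_model5)

  build_nb <- function(par) {
    p <- as.list(par)
    tEN6 <- p$T_EN6_split
    tCH <- tEN6 + p$dT_CH_split
    tTR <- tCH + p$dT_TR_split
    ev <- data.frame(
      time_gen = c(tEN6, tCH, tTR), type = "split",
      pop = c("EN6", "CH", "EN1"), dest = c("EN1", "EN1", "TR"),
      Ne = c(NA, .M5$N_EN_PRE, p$N_ANC), stringsAsFactors = FALSE)
    DemographicModel(c("TR", "CH", "EN1", "EN6"),
                     c(p$N_TR, .M5$N_CH, .M5$N_EN1, .M5$N_EN6),
                     ev, mu = 1.23e-8, generationTime = 2)
  }
  nb <- modelTemplate("nobottleneck", par, lower, upper, build_nb,
                      report = .report_model5)

  build_sb <- function(par) {
    p <- as.list(par)
    tEN6 <- p$T_EN6_split
    tCH <- tEN6 + p$dT_CH_split
    tTR <- tCH + p$dT_TR_split
    ev <- data.frame(
      time_gen = c(tEN6, .M5$T_EN_REC, .M5$T_EN_BOT, tCH, tTR),
      type = c("split", "size", "size", "split", "split"),
      pop = c("EN6", "EN1", "EN1", "CH", "EN1"),
      dest = c("EN1", NA, NA, "EN1", "TR"),
      Ne = c(NA, .M5$N_EN_BOT, .M5$N_EN_PRE, .M5$N_EN_PRE, p$N_ANC),
      stringsAsFactors = FALSE)
    merge_time <- c(EN6 = tEN6, CH = tCH, EN1 = tTR, TR = Inf)
    ev <- ev[ev$type == "split" | ev$time_gen < merge_time[ev$pop], ,
             drop = FALSE]
    DemographicModel(c("TR", "CH", "EN1", "EN6"),
                     c(p$N_TR, .M5$N_CH, .M5$N_EN1, .M5$N_EN6),
                     ev, mu = 1.23e-8, generationTime = 2)
  }
  sb <- modelTemplate("singlebottleneck", par, lower, upper, build_sb,
                      report = .report_model5)

  list(model5 = m5, nobottleneck = nb, singlebottleneck = sb)
}

#' Read a demographic model from a structured YAML file
#'
#' The file must carry explicit \code{ne_units} ("diploid") and
#' \code{time_units} ("years" or "generations") tags; times in years are
#' converted with the declared generation time. See
#' \code{system.file("extdata", "model5.yaml", package = "primrose")} for an
#' example encoding the best-fit expansion history.
#'
#' @param path YAML model file
#' @return a \linkS4class{DemographicModel}
#' @export
readDemographicModel <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (need in c("ne_units", "time_units", "populations", "ne"))
    if (is.null(cfg[[need]])) stop("model file missing required tag: ", need)
  if (!identical(cfg$ne_units, "diploid"))
    stop("ne_units must be 'diploid' (haploid gene-copy counts are not assumed)")
  g <- if (is.null(cfg$generation_time)) 2 else cfg$generation_time
  tconv <- switch(cfg$time_units, years = function(t) t / g,
                  generations = identity,
                  stop("time_units must be 'years' or 'generations'"))
  ev <- if (length(cfg$events)) {
    do.call(rbind, lapply(cfg$events, function(e) data.frame(
      time_gen = tconv(e$time), type = e$type, pop = e$pop,
      dest = if (is.null(e$dest)) NA_character_ else e$dest,
      Ne = if (is.null(e$ne)) NA_real_ else e$ne,
      stringsAsFactors = FALSE)))
  } else NULL
  DemographicModel(unlist(cfg$populations), unlist(cfg$ne),
                   events = if (is.null(ev)) data.frame(
                     time_gen = numeric(), type = character(),
                     pop = character(), dest = character(), Ne = numeric())
                   else ev,
                   mu = if (is.null(cfg$mu)) 1.23e-8 else cfg$mu,
                   generationTime = g)
}
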