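.SOURCES <- c("environment", "rep_in_env", "block_in_rep_env", "hybrid",
              "line_gca", "tester_gca", "line_x_tester_sca", "hybrid_x_env",
              "line_x_env", "tester_x_env", "line_x_tester_x_env", "error")

# Sequential (type-I) decomposition: each element of `terms` is a factor;
# SS of a term is the drop in residual SS when its dummy columns join the
# cumulative design matrix, df the gain in column rank. Rank-deficient
# matrices are handled by the pivoted QR inside lm.fit, so least squares on
# available data is what an unbalanced core falls back to.
.sequentialSS <- function(y, terms) {
  X <- matrix(1, length(y), 1)
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  rank <- fit$rank
  out <- data.frame(term = names(terms), df = NA_real_, ss = NA_real_)
  for (i in seq_along(terms)) {
    f <- droplevels(as.factor(terms[[i]]))
    ind <- vapply(levels(f), function(L) as.numeric(f == L),
                  numeric(length(f)))   # plain indicators: no contrasts
    X <- cbind(X, ind)
    fit <- stats::lm.fit(X, y)
    rss_i <- sum(fit$residuals^2)
    out$df[i] <- fit$rank - rank
    out$ss[i] <- rss - rss_i
    rss <- rss_i
    rank <- fit$rank
  }
  list(table = out, rss = rss, errorDf = length(y) - rank)
}

#' Multi-environment line x tester ANOVA
#'
#' Sequential (type-I) analysis of variance for the testcross core of a
#' line x tester trial, in the canonical source order: Environment,
#' Rep(Env), Block(Env x Rep), Hybrid partitioned into Line (GCA), Tester
#' (GCA) and Line x Tester (SCA), the matching environment interactions, and
#' Error. Checks and the tester-cross entry are excluded before the hybrid
#' degrees of freedom are partitioned. The incomplete-block (alpha-lattice)
#' adjustment is the sequential block-within-rep term; no inter-block
#' information is recovered.
#'
#' F ratios for the genetic terms (hybrid, line, tester, line x tester) use
#' the corresponding x Environment mean square when that term is fitted
#' (environments random, hybrids fixed), otherwise the error mean square;
#' Environment is tested against Rep(Env); all remaining terms against
#' Error. With a single environment the interaction rows are omitted.
#'
#' An incomplete testcross core (missing cells or missing plots) triggers a
#' warning, a least-squares fit on the available data, and `balanced =
#' FALSE`; in balanced data the hybrid SS decomposes exactly into the line,
#' tester and line x tester SS.
#'
#' @param x a [TrialData-class] object.
#' @param trait trait column name.
#' @param condition `"infested"`, `"non_infested"` or `"across_mtl"`.
#' @return an [AnovaTable-class] object.
#' @examples
#' sim <- simulateTrial(trialSimConfig(nLines = 4), seed = 7)
#' anovaLineByTester(sim$trial, "grain_yield", "non_infested")
#' @export
anovaLineByTester <- function(x, trait,
                              condition = c("across_mtl", "infested",
                                            "non_infested")) {
  condition <- match.arg(condition)
  stopifnot(trait %in% traitNames(x))
  rec <- records(x)
  if (condition != "across_mtl") rec <- rec[rec$condition == condition, ]
  rec <- rec[rec$entry_role == "testcross", ]
  if (!nrow(rec)) stop("no testcross records for condition ", condition)
  miss <- is.na(rec[[trait]])
  if (any(miss)) rec <- rec[!miss, ]

  des <- trialDesign(x)
  l <- length(des@lines); t <- length(des@testers)
  env <- factor(rec$environment)
  e <- nlevels(env)
  r <- des@replicates
  line <- factor(rec$line, levels = des@lines)
  tester <- factor(rec$tester, levels = des@testers)
  repf <- interaction(env, rec$replicate, drop = TRUE)
  blockf <- interaction(repf, rec$block, drop = TRUE)

  counts <- table(line, tester, env)
  balanced <- !any(miss) && length(unique(as.vector(counts))) == 1 &&
    counts[1] == r
  if (!balanced)
    warning("testcross core is not balanced; ",
            "fitting least squares on available data")

  y <- rec[[trait]]
  terms <- list(environment = env,
                rep_in_env = repf,
                block_in_rep_env = blockf,
                line_gca = line,
                tester_gca = tester,
                line_x_tester_sca = interaction(line, tester, drop = TRUE))
  withEnv <- e >= 2
  if (withEnv)
    terms <- c(terms, list(
      line_x_env = interaction(line, env, drop = TRUE),
      tester_x_env = interaction(tester, env, drop = TRUE),
      line_x_tester_x_env = interaction(line, tester, env, drop = TRUE)))
  seq <- .sequentialSS(y, terms)
  tab <- seq$table

  get <- function(term, col) tab[[col]][tab$term == term]
  row <- function(source, df, ss)
    data.frame(source = source, df = df, ss = ss,
               ms = ifelse(df > 0, ss / df, NA_real_))
  hyb_df <- get("line_gca", "df") + get("tester_gca", "df") +
    get("line_x_tester_sca", "df")
  hyb_ss <- get("line_gca", "ss") + get("tester_gca", "ss") +
    get("line_x_tester_sca", "ss")
  out <- rbind(
    if (withEnv) row("environment", get("environment", "df"),
                     get("environment", "ss")),
    row("rep_in_env", get("rep_in_env", "df"), get("rep_in_env", "ss")),
    row("block_in_rep_env", get("block_in_rep_env", "df"),
        get("block_in_rep_env", "ss")),
    row("hybrid", hyb_df, hyb_ss),
    row("line_gca", get("line_gca", "df"), get("line_gca", "ss")),
    row("tester_gca", get("tester_gca", "df"), get("tester_gca", "ss")),
    row("line_x_tester_sca", get("line_x_tester_sca", "df"),
        get("line_x_tester_sca", "ss")))
  if (withEnv) {
    he_df <- get("line_x_env", "df") + get("tester_x_env", "df") +
      get("line_x_tester_x_env", "df")
    he_ss <- get("line_x_env", "ss") + get("tester_x_env", "ss") +
      get("line_x_tester_x_env", "ss")
    out <- rbind(out,
      row("hybrid_x_env", he_df, he_ss),
      row("line_x_env", get("line_x_env", "df"), get("line_x_env", "ss")),
      row("tester_x_env", get("tester_x_env", "df"),
          get("tester_x_env", "ss")),
      row("line_x_tester_x_env", get("line_x_tester_x_env", "df"),
          get("line_x_tester_x_env", "ss")))
  } else {
    message("single environment: interaction-with-environment rows omitted")
  }
  out <- rbind(out, row("error", seq$errorDf, seq$rss))

  ms_of <- function(source) {
    i <- match(source, out$source)
    if (is.na(i)) NA_real_ else out$ms[i]
  }
  df_of <- function(source) {
    i <- match(source, out$source)
    if (is.na(i)) NA_real_ else out$df[i]
  }
  denom <- c(environment = "rep_in_env", rep_in_env = "error",
             block_in_rep_env = "error",
             hybrid = if (withEnv) "hybrid_x_env" else "error",
             line_gca = if (withEnv) "line_x_env" else "error",
             tester_gca = if (withEnv) "tester_x_env" else "error",
             line_x_tester_sca = if (withEnv) "line_x_tester_x_env"
                                 else "error",
             hybrid_x_env = "error", line_x_env = "error",
             tester_x_env = "error", line_x_tester_x_env = "error")
  out$f <- NA_real_
  out$p <- NA_real_
  for (i in seq_len(nrow(out))) {
    src <- out$source[i]
    if (src == "error" || !src %in% names(denom)) next
    dms <- ms_of(denom[[src]]); ddf <- df_of(denom[[src]])
    if (is.na(dms) || is.na(ddf) || ddf <= 0 || dms <= 0 ||
        is.na(out$ms[i])) next
    out$f[i] <- out$ms[i] / dms
    out$p[i] <- pf(out$f[i], out$df[i], ddf, lower.tail = FALSE)
  }
  closed <- c(line_gca = l - 1, tester_gca = t - 1,
              line_x_tester_sca = (l - 1) * (t - 1))
  dfOk <- all(out$df[match(names(closed), out$source)] == closed)
  rownames(out) <- NULL
  new("AnovaTable", table = out, trait = trait, condition = condition,
      balanced = balanced && dfOk, nLines = as.integer(l),
      nTesters = as.integer(t), nEnv = as.integer(e), nRep = as.integer(r))
}

#' Significance codes on the 0.05 / 0.01 / 0.001 / 0.0001 ladder
#'
#' @param p numeric p-values.
#' @return character: `"*"`, `"**"`, `"***"`, `"†"` (p < 0.0001) or "".
#' @export
signifCodes <- function(p) {
  out <- character(length(p))
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.01] <- "**"
  out[!is.na(p) & p < 0.001] <- "***"
  out[!is.na(p) & p < 1e-4] <- "†"
  out
}

#' GCA, SCA and HSGCA effects with standard errors
#'
#' Kempthorne line x tester estimation from raw testcross cell means:
#' `g_i = x_i.. - x...`, `g_j = x_.j. - x...`,
#' `s_ij = x_ij. - x_i.. - x_.j. + x...`, and
#' `hsgca_ij = g_i + s_ij` (equivalently the i x j testcross mean minus the
#' tester-j mean in balanced data). Standard errors use the combined-ANOVA
#' error mean square: `SE(g_line) = sqrt(MSE/(r e t))`, `SE(g_tester) =
#' sqrt(MSE/(r e l))`, `SE(s) = sqrt(MSE/(r e))`; two-sided t tests on the
#' error degrees of freedom give the p-values.
#'
#' The centering identities hold for every input: line and tester GCA sum to
#' zero, SCA rows and columns sum to zero, and with exactly two testers the
#' tester GCAs are equal and opposite.
#'
#' @param x a [TrialData-class] object.
#' @param trait trait column name.
#' @param condition `"infested"`, `"non_infested"` or `"across_mtl"`.
#' @return a [CombiningAbility-class] object.
#' @examples
#' sim <- simulateTrial(trialSimConfig(nLines = 4), seed = 7)
#' ca <- estimateGcaSca(sim$trial, "grain_yield", "non_infested")
#' gcaTester(ca)   # equal and opposite with two testers
#' @export
estimateGcaSca <- function(x, trait,
                           condition = c("across_mtl", "infested",
                                         "non_infested")) {
  condition <- match.arg(condition)
  m <- testcrossMeanMatrix(x, trait, condition)
  if (anyNA(m)) stop("missing testcross cell mean(s); cannot estimate ",
                     "combining ability")
  grand <- mean(m)
  gL <- rowMeans(m) - grand
  gT <- colMeans(m) - grand
  sca <- sweep(sweep(m, 1, rowMeans(m)), 2, colMeans(m)) + grand
  hsgca <- sweep(m, 2, colMeans(m))

  an <- suppressWarnings(anovaLineByTester(x, trait, condition))
  tab <- as.data.frame(an)
  mse <- tab$ms[tab$source == "error"]
  dfErr <- tab$df[tab$source == "error"]
  r <- an@nRep; e <- an@nEnv
  l <- nrow(m); t <- ncol(m)
  if (is.na(dfErr) || dfErr <= 0 || is.na(mse)) {
    warning("zero error degrees of freedom: effects returned without ",
            "standard errors or significance")
    seL <- seT <- seS <- NA_real_
    pL <- setNames(rep(NA_real_, l), rownames(m))
    pT <- setNames(rep(NA_real_, t), colnames(m))
    pS <- matrix(NA_real_, l, t, dimnames = dimnames(m))
  } else {
    seL <- sqrt(mse / (r * e * t))
    seT <- sqrt(mse / (r * e * l))
    seS <- sqrt(mse / (r * e))
    pv <- function(eff, se) 2 * pt(-abs(eff / se), dfErr)
    pL <- pv(gL, seL); pT <- pv(gT, seT); pS <- pv(sca, seS)
  }
  new("CombiningAbility", trait = trait, condition = condition,
      gcaLine = gL, gcaTester = gT, sca = sca, hsgca = hsgca,
      seGcaLine = seL, seGcaTester = seT, seSca = seS,
      pGcaLine = pL, pGcaTester = pT, pSca = pS,
      mse = if (length(mse)) mse else NA_real_,
      errorDf = if (length(dfErr)) dfErr else 0)
}

.msRow <- function(tab, source) {
  i <- match(source, tab$source)
  if (is.na(i)) NA_real_ else tab$ms[i]
}

.truncate0 <- function(vals) {
  flagged <- names(vals)[!is.na(vals) & vals < 0]
  vals[!is.na(vals) & vals < 0] <- 0
  list(vals = vals, truncated = flagged)
}

#' Variance components, heritability and the additive/dominance conversion
#'
#' Method-of-moments estimation by equating observed to expected mean
#' squares in the balanced line x tester mixed model (hybrids fixed,
#' environments and their interactions random):
#' `s2_sca = (MS_lt - MS_lte)/(r e)`, `s2_gca_line = (MS_l - MS_le)/(r e t)`,
#' `s2_gca_tester = (MS_t - MS_te)/(r e l)`, with the interaction components
#' `s2_le = (MS_le - MSE)/(r t)`, `s2_te = (MS_te - MSE)/(r l)` and
#' `s2_lte = (MS_lte - MSE)/r`. Without environment-interaction rows (single
#' environment) the error mean square is the subtraction baseline and the
#' method note says so. Negative solutions are truncated at zero and
#' flagged.
#'
#' With both parents inbred to coefficient `inbreeding` (F, default 1 for
#' fully inbred lines), `s2_A = 4/(1+F) * (s2_gca_line + s2_gca_tester)` and
#' `s2_D = 4/(1+F)^2 * s2_sca`; at F = 1 these reduce to
#' `2*(s2_gca_line + s2_gca_tester)` and `s2_sca`. Narrow-sense heritability
#' on an entry-mean basis is
#' `h2 = s2_A / (s2_A + s2_D + s2_GE/e + s2_error/(r e))` with
#' `s2_GE = s2_le + s2_te + s2_lte`.
#'
#' @param anova an [AnovaTable-class] from [anovaLineByTester()].
#' @param design the [LxTDesign-class] (supplies l and t; e and r are taken
#'   from the ANOVA).
#' @param inbreeding parental inbreeding coefficient F in [0, 1].
#' @return a [VarianceComponents-class] object.
#' @export
estimateVarianceComponents <- function(anova, design, inbreeding = 1) {
  stopifnot(is(anova, "AnovaTable"), inbreeding >= 0, inbreeding <= 1)
  tab <- as.data.frame(anova)
  l <- anova@nLines; t <- anova@nTesters
  e <- anova@nEnv; r <- anova@nRep
  mse <- .msRow(tab, "error")
  ms_l <- .msRow(tab, "line_gca")
  ms_t <- .msRow(tab, "tester_gca")
  ms_lt <- .msRow(tab, "line_x_tester_sca")
  ms_le <- .msRow(tab, "line_x_env")
  ms_te <- .msRow(tab, "tester_x_env")
  ms_lte <- .msRow(tab, "line_x_tester_x_env")
  if (is.na(ms_le)) {
    message("no environment-interaction rows: components computed against ",
            "the error mean square")
    ms_le <- ms_te <- ms_lte <- mse
    s2_le <- s2_te <- s2_lte <- 0
  } else {
    s2_le <- (ms_le - mse) / (r * t)
    s2_te <- (ms_te - mse) / (r * l)
    s2_lte <- (ms_lte - mse) / r
  }
  comp <- c(sigma2_gca_line = (ms_l - ms_le) / (r * e * t),
            sigma2_gca_tester = (ms_t - ms_te) / (r * e * l),
            sigma2_sca = (ms_lt - ms_lte) / (r * e),
            sigma2_line_x_env = s2_le,
            sigma2_tester_x_env = s2_te,
            sigma2_sca_x_env = s2_lte,
            sigma2_error = mse)
  tr <- .truncate0(comp)
  comp <- tr$vals
  s2A <- 4 / (1 + inbreeding) *
    (comp[["sigma2_gca_line"]] + comp[["sigma2_gca_tester"]])
  s2D <- 4 / (1 + inbreeding)^2 * comp[["sigma2_sca"]]
  s2GE <- comp[["sigma2_line_x_env"]] + comp[["sigma2_tester_x_env"]] +
    comp[["sigma2_sca_x_env"]]
  denomH <- s2A + s2D + s2GE / e + comp[["sigma2_error"]] / (r * e)
  h2 <- if (denomH > 0) s2A / denomH else 0
  comp <- c(comp, sigma2_A = s2A, sigma2_D = s2D, h2_narrow = h2,
            repeatability = repeatability(anova, design))
  new("VarianceComponents", components = comp, truncated = tr$truncated,
      inbreeding = inbreeding, nEnv = as.integer(e), nRep = as.integer(r))
}

#' Entry-mean repeatability
#'
#' `R = s2_h / (s2_h + s2_hxe/e + s2_error/(r e))` with
#' `s2_h = (MS_hybrid - MS_hybrid_x_env)/(r e)` and
#' `s2_hxe = (MS_hybrid_x_env - MSE)/r`; negative solutions are truncated at
#' zero, so R lies in [0, 1]. With a single environment
#' `s2_h = (MS_hybrid - MSE)/(r e)` and the G x E term is dropped.
#'
#' @param anova an [AnovaTable-class] with the hybrid rows.
#' @param design the trial [LxTDesign-class] (unused beyond interface
#'   symmetry; e and r come from the ANOVA).
#' @return repeatability in [0, 1].
#' @export
repeatability <- function(anova, design) {
  stopifnot(is(anova, "AnovaTable"))
  tab <- as.data.frame(anova)
  e <- anova@nEnv; r <- anova@nRep
  mse <- .msRow(tab, "error")
  ms_h <- .msRow(tab, "hybrid")
  ms_he <- .msRow(tab, "hybrid_x_env")
  if (is.na(ms_h)) stop("ANOVA table has no hybrid row")
  if (is.na(ms_he)) {
    s2h <- max((ms_h - mse) / (r * e), 0)
    s2he <- 0
  } else {
    s2h <- max((ms_h - ms_he) / (r * e), 0)
    s2he <- max((ms_he - mse) / r, 0)
  }
  denom <- s2h + s2he / e + mse / (r * e)
  if (denom <= 0) return(0)
  s2h / denom
}

#' Least significant difference for entry means
#'
#' `LSD = t(1 - alpha/2, df_error) * sqrt(2 MSE / (r e))`, the yield gate
#' used by the SCA + yield heterotic-group classifier.
#'
#' @param anova an [AnovaTable-class] from the combined analysis.
#' @param alpha significance level (default 0.05).
#' @return LSD in trait units.
#' @export
lsdMeans <- function(anova, alpha = 0.05) {
  stopifnot(is(anova, "AnovaTable"), alpha > 0, alpha < 1)
  tab <- as.data.frame(anova)
  mse <- .msRow(tab, "error")
  dfErr <- tab$df[tab$source == "error"]
  r <- anova@nRep; e <- anova@nEnv
  qt(1 - alpha / 2, dfErr) * sqrt(2 * mse / (r * e))
}

#' Combining-ability results as a report table
#'
#' @param ca a [CombiningAbility-class] object.
#' @return data.frame with one row per line: GCA, significance code, and
#'   per-tester SCA and HSGCA columns; tester GCAs and the standard errors
#'   are appended as attributes-free final rows (`.tester:` prefixed).
#' @export
combiningAbilityTable <- function(ca) {
  stopifnot(is(ca, "CombiningAbility"))
  testers <- colnames(ca@sca)
  df <- data.frame(line = names(ca@gcaLine),
                   gca = as.numeric(ca@gcaLine),
                   gca_p = as.numeric(ca@pGcaLine),
                   gca_sig = signifCodes(ca@pGcaLine))
  for (j in testers) {
    df[[paste0("sca_", j)]] <- ca@sca[, j]
    df[[paste0("sca_p_", j)]] <- ca@pSca[, j]
    df[[paste0("hsgca_", j)]] <- ca@hsgca[, j]
  }
  extra <- data.frame(line = c(paste0(".tester:", testers),
                               ".se_gca_line", ".se_gca_tester", ".se_sca"),
                      gca = c(as.numeric(ca@gcaTester), ca@seGcaLine,
                              ca@seGcaTester, ca@seSca),
                      gca_p = c(as.numeric(ca@pGcaTester),
                                rep(NA_real_, 3)),
                      gca_sig = c(signifCodes(ca@pGcaTester), "", "", ""))
  for (nm in setdiff(names(df), names(extra))) extra[[nm]] <- NA_real_
  rownames(df) <- rownames(extra) <- NULL
  rbind(df, extra[names(df)])
}
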