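#' Standard heterosis against the tester-cross check
#'
#' `H = 100 * (F1 - CK) / CK`, where `F1` is the testcross mean and `CK` the
#' mean of the hybrid between the two testers. Vectorised over `f1`.
#'
#' @param f1 testcross trait value(s).
#' @param ck check (tester1 x tester2) trait value, non-zero.
#' @return heterosis in percent; positive when the testcross exceeds the
#'   check.
#' @examples
#' standardHeterosis(1210, 1000)  # +21
#' standardHeterosis(950, 1000)   # -5
#' @export
standardHeterosis <- function(f1, ck) {
  if (length(ck) != 1 || is.na(ck) || ck == 0)
    stop("check mean must be a single non-zero value")
  100 * (f1 - ck) / ck
}

#' Grain-yield loss under infestation
#'
#' `100 * (y_non - y_inf) / y_non`. A negative value (infested exceeding
#' non-infested) is returned with attribute `gain = TRUE`.
#'
#' @param yNonInfested non-infested yield, > 0.
#' @param yInfested infested yield.
#' @return percent yield loss (attribute `gain` flags negative losses).
#' @examples yieldLoss(5000, 1000)  # 80
#' @export
yieldLoss <- function(yNonInfested, yInfested) {
  if (any(is.na(yNonInfested)) || any(yNonInfested <= 0))
    stop("non-infested yield must be positive")
  loss <- 100 * (yNonInfested - yInfested) / yNonInfested
  attr(loss, "gain") <- any(loss < 0)
  loss
}

#' Heterosis table for every entry of a trial
#'
#' Computes standard heterosis for each testcross (and check) against the
#' design's tester-cross entry, per condition and trait.
#'
#' @param x a [TrialData-class] object whose design declares a
#'   `testerCross` check.
#' @param trait trait column name.
#' @param condition `"infested"`, `"non_infested"` or `"across_mtl"`.
#' @return data.frame: entry, line, tester, entry_role, f1, ck, h_percent.
#' @export
heterosisTable <- function(x, trait,
                           condition = c("across_mtl", "infested",
                                         "non_infested")) {
  condition <- match.arg(condition)
  des <- trialDesign(x)
  ckEntry <- testerCross(des)
  if (is.na(ckEntry)) stop("design has no tester-cross check entry")
  cm <- cellMeans(x, trait, condition)
  ck <- cm$mean[cm$entry == ckEntry]
  if (!length(ck) || is.na(ck))
    stop("no observations for the tester-cross check ", ckEntry)
  out <- cm[cm$entry != ckEntry,
            c("entry", "line", "tester", "entry_role", "mean")]
  names(out)[names(out) == "mean"] <- "f1"
  out$ck <- ck
  out$h_percent <- standardHeterosis(out$f1, ck)
  rownames(out) <- NULL
  out
}

.GROUP_OF_TESTER <- function(testers) {
  # fixed mapping: evidence with the first tester assigns the OPPOSITE
  # group (T1 represents HGA, so lines combining well with it join HGB)
  setNames(c("HGB", "HGA"), testers[1:2])
}

#' Heterotic grouping from SCA effects and testcross yields
#'
#' A line joins the group opposite its favourable tester when (i) its SCA
#' with that tester exceeds `scaThreshold` (default 100 kg/ha for grain
#' yield), (ii) its SCA with the other tester is negative, and (iii) its
#' testcross mean with the favourable tester is not significantly below the
#' tester-cross mean (`mean >= ckMean - lsd`). Evidence with tester 1
#' assigns HGB, evidence with tester 2 assigns HGA; lines failing any gate
#' stay unassigned with the reason recorded.
#'
#' @param ca a [CombiningAbility-class] object (two testers).
#' @param means lines x testers matrix of testcross means (e.g. from
#'   [testcrossMeanMatrix()]).
#' @param ckMean mean of the tester-cross check (trait units).
#' @param lsd least significant difference for entry means, > 0 (see
#'   [lsdMeans()]).
#' @param scaThreshold positive-SCA threshold in trait units (the default
#'   100 is meaningful for grain yield in kg/ha only).
#' @param condition label stored on the output rows.
#' @return data.frame: line, method, condition, group, favored_tester, sca
#'   with both testers, testcross mean, ck_mean, lsd, reason.
#' @export
assignGroupsScaYield <- function(ca, means, ckMean, lsd, scaThreshold = 100,
                                 condition = ca@condition) {
  stopifnot(is(ca, "CombiningAbility"))
  sca <- scaEffects(ca)
  if (ncol(sca) != 2)
    stop("SCA + yield grouping requires exactly two testers")
  if (is.na(lsd) || lsd <= 0) stop("lsd must be positive")
  testers <- colnames(sca)
  groupOf <- .GROUP_OF_TESTER(testers)
  out <- data.frame(line = rownames(sca), method = "sca_yield",
                    condition = condition, group = "unassigned",
                    favored_tester = NA_character_,
                    sca_t1 = sca[, 1], sca_t2 = sca[, 2],
                    testcross_mean = NA_real_, ck_mean = ckMean, lsd = lsd,
                    reason = "", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(sca))) {
    ln <- rownames(sca)[i]
    for (j in 1:2) {
      other <- 3 - j
      mn <- means[ln, testers[j]]
      if (is.na(sca[i, j]) || is.na(sca[i, other])) {
        out$reason[i] <- "insufficient data"
        next
      }
      if (sca[i, j] > scaThreshold && sca[i, other] < 0) {
        if (is.na(mn)) {
          out$reason[i] <- "insufficient data"
        } else if (mn >= ckMean - lsd) {
          out$group[i] <- groupOf[[testers[j]]]
          out$favored_tester[i] <- testers[j]
          out$testcross_mean[i] <- mn
          out$reason[i] <- "sca and yield gates passed"
        } else {
          out$testcross_mean[i] <- mn
          out$reason[i] <- "yield gate failed"
        }
      }
    }
    if (out$group[i] == "unassigned" && out$reason[i] == "")
      out$reason[i] <- "sca below threshold"
  }
  rownames(out) <- NULL
  out
}

#' Heterotic grouping from HSGCA effects
#'
#' Positive HSGCA with tester 1 assigns HGB; positive HSGCA with tester 2
#' assigns HGA. When both HSGCA values share a sign, the tie rule decides:
#' under `"min_value"` (default, reading "largest negative" as most
#' negative) the tester with the smaller HSGCA decides and the line takes
#' that tester's mapped group; `"max_value"` encodes the alternative
#' closest-to-zero reading for shared-negative pairs. Values within
#' `epsilon` of zero are treated as neither positive nor negative; a line
#' whose evidence all falls in that dead zone, or with a missing HSGCA, is
#' left unassigned.
#'
#' @param hsgca lines x 2 matrix of HSGCA effects (e.g.
#'   [hsgcaEffects()]).
#' @param tieRule `"min_value"` or `"max_value"`.
#' @param epsilon dead-zone half-width around zero (default 0).
#' @param condition label stored on the output rows.
#' @return data.frame: line, method, condition, group, hsgca with both
#'   testers, tie_rule, reason.
#' @export
assignGroupsHsgca <- function(hsgca, tieRule = c("min_value", "max_value"),
                              epsilon = 0, condition = "across_mtl") {
  tieRule <- match.arg(tieRule)
  if (is(hsgca, "CombiningAbility")) {
    condition <- hsgca@condition
    hsgca <- hsgcaEffects(hsgca)
  }
  if (ncol(hsgca) != 2)
    stop("HSGCA grouping requires exactly two testers")
  testers <- colnames(hsgca)
  groupOf <- .GROUP_OF_TESTER(testers)
  out <- data.frame(line = rownames(hsgca), method = "hsgca",
                    condition = condition, group = "unassigned",
                    hsgca_t1 = hsgca[, 1], hsgca_t2 = hsgca[, 2],
                    tie_rule = tieRule, reason = "",
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(hsgca))) {
    v <- hsgca[i, ]
    if (anyNA(v)) { out$reason[i] <- "missing HSGCA value"; next }
    pos <- v > epsilon
    neg <- v < -epsilon
    if (pos[1] && !pos[2]) {
      out$group[i] <- groupOf[[testers[1]]]
      out$reason[i] <- "positive with tester 1 only"
    } else if (pos[2] && !pos[1]) {
      out$group[i] <- groupOf[[testers[2]]]
      out$reason[i] <- "positive with tester 2 only"
    } else if (!pos[1] && !pos[2] && !neg[1] && !neg[2]) {
      out$reason[i] <- "both values within the dead zone"
    } else {
      j <- if (tieRule == "min_value") which.min(v) else which.max(v)
      out$group[i] <- groupOf[[testers[j]]]
      out$reason[i] <- paste0("same sign with both testers; tie rule ",
                              tieRule, " picked ", testers[j])
    }
  }
  rownames(out) <- NULL
  out
}

#' Consensus heterotic group across conditions
#'
#' Per line (and method): the consensus group when every non-unassigned
#' condition call agrees; `"inconsistent"` when calls disagree;
#' `"unassigned"` when no condition produced a call. The number of
#' conditions behind each consensus is reported as coverage.
#'
#' @param assignments data.frame(s) from [assignGroupsScaYield()] or
#'   [assignGroupsHsgca()], covering at least two conditions (rbind them).
#' @return data.frame: line, method, consensus, n_conditions, n_assigned.
#' @export
consensusGroups <- function(assignments) {
  if (is.list(assignments) && !is.data.frame(assignments))
    assignments <- do.call(rbind, assignments)
  stopifnot(all(c("line", "method", "condition", "group") %in%
                  names(assignments)))
  if (length(unique(assignments$condition)) < 2)
    stop("consensus needs assignments from at least two conditions")
  key <- interaction(assignments$line, assignments$method, drop = TRUE)
  rows <- lapply(split(assignments, key), function(d) {
    calls <- d$group[d$group != "unassigned"]
    consensus <- if (!length(calls)) "unassigned"
      else if (length(unique(calls)) == 1) unique(calls)
      else "inconsistent"
    data.frame(line = d$line[1], method = d$method[1],
               consensus = consensus,
               n_conditions = nrow(d), n_assigned = length(calls),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$method, out$line), , drop = FALSE]
}
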