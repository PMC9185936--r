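# Fixtures built in code: a tiny hand-specified trial and a generic
# balanced-trial builder used by the oracle tests.

toyDesign <- function(lines = c("L1", "L2"), testers = c("T1", "T2"),
                      replicates = 2) {
  LxTDesign(lines = lines, testers = testers, checks = "TCROSS",
            testerCross = "TCROSS", replicates = replicates)
}

# balanced testcross-only records with a single complete block per rep;
# cellFun(line, tester) gives the expected cell mean, noise added on top
balancedRecords <- function(lines, testers, envs, reps,
                            cellFun = function(l, t) 0,
                            envEff = setNames(rep(0, length(envs)), envs),
                            noiseSd = 0, condition = "non_infested") {
  grid <- expand.grid(line = lines, tester = testers, environment = envs,
                      replicate = seq_len(reps),
                      stringsAsFactors = FALSE)
  mu <- mapply(cellFun, grid$line, grid$tester)
  data.frame(environment = grid$environment, condition = condition,
             replicate = grid$replicate, block = "B1",
             entry = paste(grid$line, grid$tester, sep = ":"),
             entry_role = "testcross", line = grid$line,
             tester = grid$tester,
             grain_yield = mu + envEff[grid$environment] +
               rnorm(nrow(grid), 0, noiseSd),
             stringsAsFactors = FALSE)
}

balancedTrial <- function(lines = c("L1", "L2", "L3"),
                          testers = c("T1", "T2"), envs = c("E1", "E2"),
                          reps = 2, ...) {
  des <- LxTDesign(lines, testers, replicates = reps,
                   environments = list(non_infested = envs))
  TrialData(balancedRecords(lines, testers, envs, reps, ...), des,
            traits = "grain_yield")
}

# independent type-I SS oracle via the formula interface
anovaOracleSS <- function(trial, trait = "grain_yield") {
  rec <- records(trial)
  rec <- rec[rec$entry_role == "testcross" & !is.na(rec[[trait]]), ]
  rec$env <- factor(rec$environment)
  rec$repf <- interaction(rec$env, rec$replicate, drop = TRUE)
  rec$blockf <- interaction(rec$repf, rec$block, drop = TRUE)
  rec$line <- factor(rec$line)
  rec$tester <- factor(rec$tester)
  rec$y <- rec[[trait]]
  fml <- if (nlevels(rec$env) > 1)
    y ~ env + repf + blockf + line + tester + line:tester +
      line:env + tester:env + line:tester:env
  else y ~ repf + blockf + line + tester + line:tester
  a <- anova(lm(fml, data = rec))
  ss <- setNames(a[["Sum Sq"]], rownames(a))
  df <- setNames(a[["Df"]], rownames(a))
  list(ss = ss, df = df)
}

scaleFreeConfig <- function(...) {
  # unit-scale config with every nuisance variance silenced; dots override
  args <- utils::modifyList(
    list(muYield = 100, sigma2Env = 0, sigma2Rep = 0, sigma2Block = 0,
         sigma2LineEnv = 0, sigma2TesterEnv = 0, sigma2ScaEnv = 0,
         sigma2Error = 1, sigma2GcaLine = 1, sigma2GcaTester = 1,
         sigma2Sca = 0.25),
    list(...))
  do.call(trialSimConfig, args)
}
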