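#!/usr/bin/env Rscript

# Stage 4 — the trial-level behavioural GLM.
#
# Applies the exclusion rules (errors, post-errors, >2.5 s.d. RT outliers,
# post-outliers, burn-in), builds the seven-regressor design (flexible LR,
# predicted conflict, congruency, their two- and three-way interactions; the
# conflict-by-congruency column is the standardized unsigned prediction
# error |o - f|), estimates each regressor's residualized effect on reaction
# speed per subject, and tests the coefficients against zero across
# subjects. The two directional findings of interest: a negative congruency
# effect (slower responses under conflict) and a negative
# control-prediction-error modulation (slower responses when conflict was
# mispredicted).

suppressPackageStartupMessages(library(flexcontrol))

study <- readRDS(file.path("results", "study.rds"))
glm <- glm_group_effects(study$cohort)

print(glm$effects, row.names = FALSE, digits = 3)
write.csv(glm$effects, file.path("results", "glm_effects.csv"),
          row.names = FALSE)
write.csv(data.frame(subject_id = vapply(study$cohort, `[[`, "", "subject_id"),
                     glm$coefficients),
          file.path("results", "glm_subject_coefficients.csv"),
          row.names = FALSE)

cong <- glm$effects[glm$effects$label == "congruency", ]
cpe <- glm$effects[glm$effects$label == "conflict_x_congruency", ]
cat(sprintf("\ncongruency effect on RS:        t(%d) = %.2f, p = %.2g\n",
            cong$df, cong$t, cong$p))
cat(sprintf("control-prediction-error effect: t(%d) = %.2f, p = %.2g\n",
            cpe$df, cpe$t, cpe$p))
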