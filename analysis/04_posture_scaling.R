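#!/usr/bin/env Rscript
# Whole-body posture recovery across the size range of terrestrial mammals.
#
# A point-mass inverted pendulum on a leg-length lever is pushed with a
# Froude-scaled impulsive velocity (dimensionless velocity 0.21) and must
# return to rest at vertical under ankle torques. Feedback settling is
# measured on the angular velocity (2 percent of the push velocity);
# overshoot of the angle past vertical is constrained to zero. The
# available time is the free-fall time through the leg length.

library(neuroscale)
dir.create("results", showWarnings = FALSE)

run <- run_task_scaling("posture")
print(run)
comp <- compare_strategies(run)

fb <- run$fits$fb_time_ms
ff <- run$fits$ff_time_ms
fall <- fit_power_law(size_grid(), 1000 * available_time("posture", size_grid()))
cat(sprintf("\nfeedback response times scale as %.1f * M^%.2f ms\n",
            fb$coefficient, fb$exponent))
cat(sprintf("feedforward response times scale as %.1f * M^%.2f ms\n",
            ff$coefficient, ff$exponent))
cat(sprintf("time to fall a leg length scales as %.1f * M^%.3f ms\n",
            fall$coefficient, fall$exponent))
cat(sprintf("feedback takes %.1fx the sensorimotor delay on average\n",
            mean(comp$fb_over_t_sm)))
cat(sprintf("torque fraction grows from %.2f (1 g) to %.2f (10 t):\n",
            comp$torque_fraction[1], comp$torque_fraction[nrow(comp)]))
cat("only the largest animals become force-limited in this task\n")
cat(sprintf("feedback/feedforward ratio runs %.1f -> %.1f with size\n",
            comp$fb_ff_ratio[1], comp$fb_ff_ratio[nrow(comp)]))
cat("feedback always exceeds the time available before falling;\n")
cat("feedforward exceeds it only for the largest sizes\n")

write_scaling_report(run, comp, "results")
cat("wrote results/posture_*.csv and results/posture_summary.json\n")
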