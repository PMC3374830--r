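# Aggregated per-set reinforcement outcomes from the published experiments.
# produced  = salient words produced by the robot (simulated-reinforcement tp)
# missed    = salient words produced but not reinforced (includes heuristic
#             failures), i.e. false negatives under real reinforcement
# heuristic_failed = word reinforced but heuristic stored the wrong syllable
#             (subset of missed)
# learnt_salient / learnt_nonwords / learnt_other = lexicon contents:
#             true positives, non-word false positives, and proper but
#             non-salient words.
# set	participants	produced	missed	heuristic_failed	learnt_salient	learnt_nonwords	learnt_other
1	7	22	17	1	5	11	2
2	7	8	4	0	4	9	5
3	6	14	11	2	3	11	6
4	7	18	12	1	6	11	4
5	7	17	10	0	7	13	5
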