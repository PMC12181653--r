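# Built-in instrument definitions.
#
# Each entry declares an ordered item set, the ordinal response range, the
# subscale structure (every item belongs to at most one subscale), and the
# short node labels used in the symptom network. Users can register further
# scales by loading a file with the same layout via `read_instruments()`.
#
# itq: International Trauma Questionnaire, 12 items scored 0 ("not at all")
#   to 4 ("extremely"); six two-item dimensions, the three PTSD clusters
#   (re-experiencing, avoidance, sense of threat) plus the three
#   disturbances-in-self-organization clusters (negative self-concept,
#   affective dysregulation, disturbed relationships).
itq:
  items: [RE1, RE2, AV1, AV2, TH1, TH2, NSC1, NSC2, AD1, AD2, DR1, DR2]
  response_min: 0
  response_max: 4
  subscales:
    re_experiencing: [RE1, RE2]
    avoidance: [AV1, AV2]
    sense_of_threat: [TH1, TH2]
    negative_self_concept: [NSC1, NSC2]
    affective_dysregulation: [AD1, AD2]
    disturbed_relationships: [DR1, DR2]

# phq9: Patient Health Questionnaire-9, depressive symptoms over the past
#   two weeks, 9 items scored 0 ("not at all") to 3 ("nearly every day").
phq9:
  items: [dep1, dep2, dep3, dep4, dep5, dep6, dep7, dep8, dep9]
  response_min: 0
  response_max: 3
  subscales: {}

# gad7: Generalized Anxiety Disorder questionnaire, 7 items scored 0-3.
gad7:
  items: [anx1, anx2, anx3, anx4, anx5, anx6, anx7]
  response_min: 0
  response_max: 3
  subscales: {}

# bpbq_victim: victim subscale of the Bullying Participant Behavior
#   Questionnaire, 10 items, past-30-days frequency scored 0 ("never") to
#   4 ("7 or more times"). Used as the adolescent victimization screen; the
#   "never" anchor is 0.
bpbq_victim:
  items: [screen_v1, screen_v2, screen_v3, screen_v4, screen_v5,
          screen_v6, screen_v7, screen_v8, screen_v9, screen_v10]
  response_min: 0
  response_max: 4
  subscales: {}

# delaware_victim: Delaware Peer Victimization Scale, 17 items on
#   victimization before age 18, scored 1 ("never") to 6 ("every day");
#   physical/verbal/relational subscales (item grouping here is the
#   package's illustrative split). The "never" anchor is 1.
delaware_victim:
  items: [dw1, dw2, dw3, dw4, dw5, dw6, dw7, dw8, dw9, dw10, dw11, dw12,
          dw13, dw14, dw15, dw16, dw17]
  response_min: 1
  response_max: 6
  subscales:
    physical: [dw1, dw2, dw3, dw4, dw5]
    verbal: [dw6, dw7, dw8, dw9, dw10, dw11]
    relational: [dw12, dw13, dw14, dw15, dw16, dw17]
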