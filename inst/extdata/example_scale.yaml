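# Example generic scale config: a 4-item mobility checklist with one
# 4-level item, demonstrating the schema accepted by load_scale().
name: mobility_check
items:
  - id: sit_to_stand
    label: Sit to stand
    section: transfers
    min: 0
    max: 2
  - id: standing_balance
    label: Standing balance
    section: balance
    min: 0
    max: 3
  - id: gait_10m
    label: 10 m walk
    section: gait
    min: 0
    max: 2
  - id: stairs
    label: Stair climbing
    section: gait
    min: 0
    max: 2
sum_groups:
  GAIT:
    - gait_10m
    - stairs
  TOTAL:
    - sit_to_stand
    - standing_balance
    - gait_10m
    - stairs
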