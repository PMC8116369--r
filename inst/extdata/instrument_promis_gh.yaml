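# PROMIS Global Health v1.2 instrument definition.
# Raw values are stored in the direction of administration; reversal and the
# 11-point -> 5-point banding are applied at recode time.  The pain-intensity
# band map below follows the official scoring convention for the numeric
# rating item; it is configuration, not code, so other short forms (or an
# updated manual) can override it.
version: "1.2"
instrument: PROMIS-GH
items:
  - id: Global01
    content: "In general, would you say your health is"
    raw_min: 1
    raw_max: 5
    reverse: false
  - id: Global02
    content: "In general, would you say your quality of life is"
    raw_min: 1
    raw_max: 5
    reverse: false
  - id: Global03
    content: "In general, how would you rate your physical health"
    raw_min: 1
    raw_max: 5
    reverse: false
  - id: Global04
    content: "In general, how would you rate your mental health, including your mood and your ability to think"
    raw_min: 1
    raw_max: 5
    reverse: false
  - id: Global05
    content: "In general, how would you rate your satisfaction with your social activities and relationships"
    raw_min: 1
    raw_max: 5
    reverse: false
  - id: Global06
    content: "To what extent are you able to carry out your everyday physical activities"
    raw_min: 1
    raw_max: 5
    reverse: false
  - id: Global07
    content: "In the past 7 days, how would you rate your pain on average (0 = no pain, 10 = worst pain imaginable)"
    raw_min: 0
    raw_max: 10
    reverse: false
    recode:
      "0": 5
      "1": 4
      "2": 4
      "3": 4
      "4": 3
      "5": 3
      "6": 3
      "7": 2
      "8": 2
      "9": 2
      "10": 1
  - id: Global08
    content: "In the past 7 days, how would you rate your fatigue on average (1 = none, 5 = very severe as administered; stored 1 = none)"
    raw_min: 1
    raw_max: 5
    reverse: true
  - id: Global09
    content: "In general, please rate how well you carry out your usual activities and roles"
    raw_min: 1
    raw_max: 5
    reverse: false
  - id: Global10
    content: "In the past 7 days, how often have you been bothered by emotional problems (stored 1 = always)"
    raw_min: 1
    raw_max: 5
    reverse: true
subscales:
  GMH: [Global02, Global04, Global05, Global10]
  GMH-2a: [Global04, Global05]
  GPH: [Global03, Global06, Global07, Global08]
  GPH-2a: [Global03, Global06]
anchor_item: Global01
standalone_items: [Global01, Global09]
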