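# Answer key for the 13-question post-scenario awareness probe.
# Categories: environment = events in the simulation room not immediately
# relevant for patient safety; sa1 = perception of clinically relevant
# elements; sa2/sa3 = open comprehension/projection questions (never
# auto-scored). Numeric items are scored with an inclusive +/-10% margin;
# question 11's key is a lower bound (saturation at or above 97%).
questions:
  - id: 1
    category: environment
    type: binary
    correct: "yes"
    text: "Did the wall clock change from analog to digital during the laryngoscopy?"
  - id: 2
    category: environment
    type: binary
    correct: "no"
    text: "Did somebody enter the room during the laryngoscopy?"
  - id: 3
    category: environment
    type: binary
    correct: "no"
    text: "Did the nurse switch the phone to the other ear during the call?"
  - id: 4
    category: environment
    type: text
    accepted: ["shift change", "shift handover"]
    text: "What was the content of the phone call?"
  - id: 5
    category: environment
    type: binary
    correct: "yes"
    text: "Did the nurse wear a watch during the laryngoscopy?"
  - id: 6
    category: environment
    type: binary
    correct: "no"
    text: "Was the blocking syringe attached to the endotracheal tube?"
  - id: 7
    category: sa1
    type: binary
    correct: "yes"
    text: "Did the anesthetic machine give a warning or alarm?"
  - id: 8
    category: environment
    type: binary
    correct: "yes"
    text: "Was one of the operating lights switched off?"
  - id: 9
    category: sa1
    type: numeric
    margin: 0.10
    items:
      - {item: systolic, correct: 116}
      - {item: diastolic, correct: 46}
    text: "What was the blood pressure of the patient?"
  - id: 10
    category: sa1
    type: numeric
    margin: 0.10
    correct: 51
    text: "What was the heart rate of the patient?"
  - id: 11
    category: sa1
    type: numeric_threshold
    direction: ge
    correct: 97
    text: "What was the oxygen saturation of the patient?"
  - id: 12
    category: sa2
    type: open
    text: "How would you describe the actual status of the patient?"
  - id: 13
    category: sa3
    type: open
    text: "Where do you see the patient's status in the next few minutes?"
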