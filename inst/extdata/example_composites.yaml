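# Example composite specifications (synthetic measure-to-domain map; the
# battery's actual map is study-specific and not shipped).
- domain: Abstraction
  metric: accuracy
  members: [matrix_correct, analogy_correct]
  directions: higher_is_better
- domain: Abstraction
  metric: speed
  members: [matrix_rt, analogy_rt]
  directions: lower_is_better
- domain: Episodic Memory
  metric: accuracy
  members: [word_recall, face_recognition, scene_recall]
  directions: higher_is_better
- domain: Total
  metric: accuracy
  members: [matrix_correct, analogy_correct, word_recall, face_recognition, scene_recall]
  directions: higher_is_better
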