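{
  "goals": [
    {"name": "Reduce back pain", "rationale": "Less pain during everyday activities"},
    {"name": "Treat leg cramps", "rationale": "Fewer and less intense cramps"},
    {"name": "Treat rheumatoid arthritis", "rationale": "Reduce joint pain and stiffness"},
    {"name": "Treat irritable bowel syndrome", "rationale": "Fewer digestive complaints"},
    {"name": "Improve sleep", "rationale": "Feel more rested during the day"},
    {"name": "Reduce stress", "rationale": "Feel calmer in daily life"}
  ],
  "interventions": [
    {"name": "Willow bark tea", "instructions": "Drink one cup of willow bark tea.", "reminder": {"times": ["09:00"], "recurrence": "daily"}},
    {"name": "Arnica gel", "instructions": "Apply arnica gel to the affected area.", "reminder": {"times": ["09:00"], "recurrence": "daily"}},
    {"name": "Warming pad", "instructions": "Use a warming pad on your back for 20 minutes.", "reminder": {"times": ["19:00"], "recurrence": "daily"}},
    {"name": "Magnesium", "instructions": "Take a magnesium supplement with a meal.", "reminder": {"times": ["08:00"], "recurrence": "daily"}},
    {"name": "Vitamin B12", "instructions": "Take a vitamin B12 supplement.", "reminder": {"times": ["08:00"], "recurrence": "daily"}},
    {"name": "Massage", "instructions": "Massage the affected muscles for 10 minutes.", "reminder": {"times": ["20:00"], "recurrence": "daily"}},
    {"name": "Omega-3 supplement", "instructions": "Take an omega-3 supplement with a meal.", "reminder": {"times": ["08:00"], "recurrence": "daily"}},
    {"name": "Olive oil massage", "instructions": "Gently massage stiff joints with olive oil.", "reminder": {"times": ["20:00"], "recurrence": "daily"}},
    {"name": "Cold patch", "instructions": "Apply a cold patch to inflamed joints for 15 minutes.", "reminder": {"times": ["19:00"], "recurrence": "daily"}},
    {"name": "Gluten-free diet", "instructions": "Avoid gluten-containing foods today.", "reminder": {"times": ["07:30"], "recurrence": "daily"}},
    {"name": "Fructose-free diet", "instructions": "Avoid fructose-rich foods today.", "reminder": {"times": ["07:30"], "recurrence": "daily"}},
    {"name": "Low-fiber diet", "instructions": "Choose low-fiber foods today.", "reminder": {"times": ["07:30"], "recurrence": "daily"}},
    {"name": "Go for a walk", "instructions": "Take a 30-minute walk outside.", "reminder": {"times": ["17:00"], "recurrence": "daily"}},
    {"name": "Meditation", "instructions": "Meditate for 10 minutes in a quiet place.", "reminder": {"times": ["21:00"], "recurrence": "daily"}}
  ],
  "measures": [
    {"name": "Pain level", "input_type": "scale", "scale_config": {"min": 0, "max": 10, "annotations": [{"position": 0, "label": "no pain"}, {"position": 10, "label": "worst imaginable pain"}]}, "reminder": {"times": ["20:00"], "recurrence": "daily"}},
    {"name": "Sleep duration", "input_type": "keyboard", "keyboard_config": {"unit": "hours"}, "reminder": {"times": ["08:00"], "recurrence": "daily"}},
    {"name": "Mood", "input_type": "scale", "scale_config": {"min": 0, "max": 10, "annotations": [{"position": 0, "label": "very low"}, {"position": 10, "label": "very good"}]}, "reminder": {"times": ["20:00"], "recurrence": "daily"}},
    {"name": "Symptoms today", "input_type": "list", "list_config": {"items": ["none", "mild", "moderate", "severe"]}, "reminder": {"times": ["20:00"], "recurrence": "daily"}}
  ],
  "links": {
    "Reduce back pain": ["Willow bark tea", "Arnica gel", "Warming pad"],
    "Treat leg cramps": ["Magnesium", "Vitamin B12", "Massage"],
    "Treat rheumatoid arthritis": ["Omega-3 supplement", "Olive oil massage", "Cold patch"],
    "Treat irritable bowel syndrome": ["Gluten-free diet", "Fructose-free diet", "Low-fiber diet"]
  }
}
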