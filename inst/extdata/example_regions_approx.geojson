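{"type":"FeatureCollection",
 "comment":"Approximate, hand-drawn rectangular stand-ins for six areas of historical interest (editable examples; NOT real political boundaries).",
 "features":[
  {"type":"Feature","properties":{"name":"Germany"},
   "geometry":{"type":"Polygon","coordinates":[[[6,47.5],[15,47.5],[15,54.5],[6,54.5],[6,47.5]]]}},
  {"type":"Feature","properties":{"name":"Ukraine"},
   "geometry":{"type":"Polygon","coordinates":[[[22,45],[40,45],[40,52],[22,52],[22,45]]]}},
  {"type":"Feature","properties":{"name":"Khazaria"},
   "geometry":{"type":"Polygon","coordinates":[[[38,41],[50,41],[50,48],[38,48],[38,41]]]}},
  {"type":"Feature","properties":{"name":"Turkish Ashkenaz"},
   "geometry":{"type":"Polygon","coordinates":[[[35,39],[42,39],[42,42],[35,42],[35,39]]]}},
  {"type":"Feature","properties":{"name":"Israel"},
   "geometry":{"type":"Polygon","coordinates":[[[34,29.5],[36,29.5],[36,33.5],[34,33.5],[34,29.5]]]}},
  {"type":"Feature","properties":{"name":"Iran"},
   "geometry":{"type":"Polygon","coordinates":[[[44,27],[60,27],[60,38],[44,38],[44,27]]]}}
 ]}
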