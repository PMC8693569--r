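.dv-widget {
  font-family: "Helvetica Neue", Helvetica, Arial, sans-serif;
  font-size: 13px;
  color: #222;
  max-width: 960px;
  margin: 0 auto;
}
.dv-controls {
  display: flex;
  flex-wrap: wrap;
  gap: 10px;
  align-items: center;
  padding: 6px 0;
  border-bottom: 1px solid #ddd;
  margin-bottom: 8px;
}
.dv-ctl select, .dv-search, .dv-maxy {
  font-size: 12px;
  padding: 2px 4px;
}
.dv-panels { display: flex; flex-wrap: wrap; gap: 16px; }
.dv-panel { flex: 1 1 300px; }
.dv-title { font-weight: bold; margin: 4px 0; }
.dv-plot { background: #fff; }
.dv-axis { stroke: #333; stroke-width: 1; }
.dv-tick { font-size: 10px; fill: #333; }
.dv-label { font-size: 11px; fill: #111; }
.dv-point { cursor: pointer; stroke: #fff; stroke-width: 0.5; }
.dv-bar { fill: #4878a8; }
.dv-genelabel { font-size: 10px; font-style: italic; fill: #000; }
.dv-btn {
  font-size: 11px;
  padding: 2px 8px;
  margin-right: 4px;
  cursor: pointer;
}
.dv-savebar { margin: 4px 0; }
.dv-legend { margin: 4px 0; font-size: 11px; }
.dv-legend-item { margin-right: 10px; }
.dv-legend-title { font-weight: bold; }
.dv-swatch {
  display: inline-block;
  width: 10px;
  height: 10px;
  border-radius: 2px;
  vertical-align: middle;
}
.dv-strip {
  padding: 6px 0;
  border-top: 1px solid #ddd;
  border-bottom: 1px solid #ddd;
  margin: 8px 0;
}
.dv-strip-label { font-weight: bold; }
.dv-strip-save { margin-left: 12px; }
.dv-tablewrap { max-height: 320px; overflow: auto; }
.dv-table { border-collapse: collapse; width: 100%; font-size: 12px; }
.dv-table th, .dv-table td {
  border: 1px solid #e0e0e0;
  padding: 2px 6px;
  text-align: left;
  white-space: nowrap;
}
.dv-table th { background: #f4f4f4; position: sticky; top: 0; }
.dv-table tr { cursor: pointer; }
.dv-table tr.dv-selected { background: #ffe9b0; }
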