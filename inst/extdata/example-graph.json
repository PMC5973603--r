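{
  "elements": [
    {
      "group": "nodes",
      "data": {
        "id": "a",
        "parent": "c1"
      },
      "position": {
        "x": 0,
        "y": 60
      },
      "dimensions": {
        "w": 30,
        "h": 30
      }
    },
    {
      "group": "nodes",
      "data": {
        "id": "b",
        "parent": "c1"
      },
      "position": {
        "x": 60,
        "y": 60
      },
      "dimensions": {
        "w": 30,
        "h": 30
      }
    },
    {
      "group": "nodes",
      "data": {
        "id": "c1"
      },
      "position": {
        "x": 65,
        "y": 25
      },
      "dimensions": {
        "w": 180,
        "h": 120
      }
    },
    {
      "group": "nodes",
      "data": {
        "id": "c2",
        "parent": "c1"
      },
      "position": {
        "x": 120,
        "y": 0
      },
      "dimensions": {
        "w": 50,
        "h": 50
      }
    },
    {
      "group": "nodes",
      "data": {
        "id": "d",
        "parent": "c1"
      },
      "position": {
        "x": 60,
        "y": 0
      },
      "dimensions": {
        "w": 30,
        "h": 30
      }
    },
    {
      "group": "nodes",
      "data": {
        "id": "e",
        "parent": "c2"
      },
      "position": {
        "x": 120,
        "y": 0
      },
      "dimensions": {
        "w": 30,
        "h": 30
      }
    },
    {
      "group": "edges",
      "data": {
        "id": "a--b",
        "source": "a",
        "target": "b"
      }
    },
    {
      "group": "edges",
      "data": {
        "id": "b--d",
        "source": "b",
        "target": "d"
      }
    },
    {
      "group": "edges",
      "data": {
        "id": "d--e",
        "source": "d",
        "target": "e"
      }
    }
  ],
  "archived_originals": []
}
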